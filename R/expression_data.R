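#' Annotated expression matrix
#'
#' Container for a cells x genes expression matrix with per-cell cell-type and
#' condition annotations. Values are raw counts on load and log-normalized
#' expression after [normalize_expression()]. Rows are cells, columns genes.
#'
#' @param values numeric matrix, cells x genes, no missing values. Row names
#'   are taken as cell ids, column names as gene names (defaults are generated
#'   when absent).
#' @param cell_types character/factor vector, one label per cell.
#' @param conditions character/factor vector, one label per cell.
#' @param normalized logical; whether `values` are already log-normalized.
#'
#' @return An object of class `aem`: a list with elements `values`,
#'   `cell_types`, `conditions`, `normalized`, and (after
#'   [restrict_to_pair()]) `condition_codes` plus `condition_levels`.
#' @export
aem <- function(values, cell_types, conditions, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("expression values contain missing/NaN entries")
  cell_types <- as.character(cell_types)
  conditions <- as.character(conditions)
  if (length(cell_types) != nrow(values) || length(conditions) != nrow(values)) {
    stop("annotation length does not match the number of cells")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("gene_%d", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("gene names must be unique")
  structure(
    list(
      values = values, cell_types = cell_types, conditions = conditions,
      normalized = isTRUE(normalized), condition_codes = NULL,
      condition_levels = NULL
    ),
    class = "aem"
  )
}

#' @export
print.aem <- function(x, ...) {
  cat(sprintf(
    "<aem> %d cells x %d genes | %d cell types | conditions: %s%s\n",
    nrow(x$values), ncol(x$values), length(unique(x$cell_types)),
    paste(sort(unique(x$conditions)), collapse = "/"),
    if (x$normalized) " | log-normalized" else ""
  ))
  invisible(x)
}

#' @export
dim.aem <- function(x) dim(x$values)

gene_names <- function(mat) colnames(mat$values)
cell_ids <- function(mat) rownames(mat$values)

aem_subset <- function(mat, idx) {
  out <- mat
  out$values <- mat$values[idx, , drop = FALSE]
  out$cell_types <- mat$cell_types[idx]
  out$conditions <- mat$conditions[idx]
  if (!is.null(mat$condition_codes)) out$condition_codes <- mat$condition_codes[idx]
  out
}

#' Per-cell annotations as a tibble
#'
#' @param x an [aem()] object.
#' @param ... unused.
#' @export
tidy.aem <- function(x, ...) {
  tibble::tibble(
    cell_id = cell_ids(x), cell_type = x$cell_types, condition = x$conditions
  )
}

# integer 0..K-1 cell-type codes, deterministic by sorted label order
cell_type_codes <- function(mat, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(mat$cell_types))
  codes <- match(mat$cell_types, levels) - 1L
  if (anyNA(codes)) stop("cell type not among the training levels")
  codes
}

condition_codes <- function(mat) {
  if (is.null(mat$condition_codes)) {
    stop("conditions are not binary-coded; call restrict_to_pair() first")
  }
  mat$condition_codes
}

find_python <- function() {
  py <- getOption("invae.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for h5ad I/O")
  py
}

h5ad_bridge <- function() {
  system.file("python", "h5ad_bridge.py", package = "invae", mustWork = TRUE)
}

#' Load an annotated expression dataset
#'
#' Reads cells x genes expression with per-cell cell-type and condition labels
#' from one of three on-disk layouts:
#' \describe{
#'   \item{csv}{one table; columns `cell_id`, the annotation columns, then one
#'     column per gene.}
#'   \item{mtx}{a directory holding `matrix.mtx` (genes x cells MatrixMarket
#'     triplets), `genes.tsv` (one gene name per line) and `cells.tsv`
#'     (tab-separated with header: cell id plus the annotation columns).}
#'   \item{h5ad}{an AnnData file; the matrix is taken from `X` and labels from
#'     the named `obs` columns (converted through a bundled Python bridge).}
#' }
#'
#' @param path file (csv, h5ad) or directory (mtx).
#' @param format one of `"auto"`, `"csv"`, `"mtx"`, `"h5ad"`. `"auto"` guesses
#'   from the file extension, directories are treated as mtx.
#' @param cell_type_col,condition_col names of the annotation columns.
#' @return An [aem()] object with labels in file order.
#' @export
load_dataset <- function(path, format = c("auto", "csv", "mtx", "h5ad"),
                         cell_type_col = "cell_type",
                         condition_col = "condition") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "mtx"
    } else if (grepl("\\.h5ad$", path, ignore.case = TRUE)) {
      "h5ad"
    } else {
      "csv"
    }
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    csv = read_aem_csv(path, cell_type_col, condition_col),
    mtx = read_aem_mtx(path, cell_type_col, condition_col),
    h5ad = read_aem_h5ad(path, cell_type_col, condition_col)
  )
}

read_aem_csv <- function(path, cell_type_col, condition_col) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(cell_type_col, condition_col)) {
    if (!col %in% names(df)) {
      stop("annotation column '", col, "' missing from ", path)
    }
  }
  id_col <- if ("cell_id" %in% names(df)) "cell_id" else NULL
  meta_cols <- c(id_col, cell_type_col, condition_col)
  gene_cols <- setdiff(names(df), meta_cols)
  vals <- df[, gene_cols, drop = FALSE]
  if (!all(vapply(vals, is.numeric, TRUE))) {
    stop("non-numeric expression values in ", path)
  }
  values <- as.matrix(vals)
  rownames(values) <- if (!is.null(id_col)) as.character(df[[id_col]]) else NULL
  aem(values, df[[cell_type_col]], df[[condition_col]])
}

read_aem_mtx <- function(path, cell_type_col, condition_col) {
  mtx_file <- file.path(path, "matrix.mtx")
  genes_file <- file.path(path, "genes.tsv")
  cells_file <- file.path(path, "cells.tsv")
  for (f in c(mtx_file, genes_file, cells_file)) {
    if (!file.exists(f)) stop("missing mtx component: ", f)
  }
  m <- Matrix::readMM(mtx_file) # genes x cells
  genes <- utils::read.delim(genes_file, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(cells_file, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(cell_type_col, condition_col)) {
    if (!col %in% names(cells)) {
      stop("annotation column '", col, "' missing from ", cells_file)
    }
  }
  if (nrow(cells) != ncol(m)) stop("cells.tsv length does not match matrix")
  if (length(genes) != nrow(m)) stop("genes.tsv length does not match matrix")
  values <- t(as.matrix(m))
  colnames(values) <- genes
  rownames(values) <- as.character(cells[[1]])
  aem(values, cells[[cell_type_col]], cells[[condition_col]])
}

read_aem_h5ad <- function(path, cell_type_col, condition_col) {
  tmp <- tempfile("h5ad_export_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  status <- system2(find_python(),
                    c(h5ad_bridge(), "export", shQuote(path), shQuote(tmp),
                      shQuote(cell_type_col), shQuote(condition_col)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("h5ad export failed: ", paste(status, collapse = "\n"))
  }
  read_aem_mtx(tmp, cell_type_col, condition_col)
}

#' Write an annotated expression dataset
#'
#' Inverse of [load_dataset()]; the same three layouts are supported.
#'
#' @param mat an [aem()] object.
#' @param path output file (csv, h5ad) or directory (mtx; created).
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`.
#' @param cell_type_col,condition_col annotation column names to write.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(mat, path, format = c("csv", "mtx", "h5ad"),
                          cell_type_col = "cell_type",
                          condition_col = "condition") {
  format <- match.arg(format)
  switch(format,
    csv = {
      df <- data.frame(
        cell_id = cell_ids(mat), check.names = FALSE,
        stringsAsFactors = FALSE
      )
      df[[cell_type_col]] <- mat$cell_types
      df[[condition_col]] <- mat$conditions
      df <- cbind(df, as.data.frame(mat$values, check.names = FALSE))
      utils::write.csv(df, path, row.names = FALSE)
    },
    mtx = {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      Matrix::writeMM(Matrix::Matrix(t(mat$values), sparse = TRUE),
                      file.path(path, "matrix.mtx"))
      writeLines(gene_names(mat), file.path(path, "genes.tsv"))
      cells <- data.frame(cell_id = cell_ids(mat), check.names = FALSE)
      cells[[cell_type_col]] <- mat$cell_types
      cells[[condition_col]] <- mat$conditions
      utils::write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    },
    h5ad = {
      tmp <- tempfile("h5ad_import_")
      write_dataset(mat, tmp, "mtx", cell_type_col, condition_col)
      on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
      status <- system2(find_python(),
                        c(h5ad_bridge(), "import", shQuote(tmp), shQuote(path),
                          shQuote(cell_type_col), shQuote(condition_col)),
                        stdout = TRUE, stderr = TRUE)
      code <- attr(status, "status")
      if (!is.null(code) && code != 0) {
        stop("h5ad import failed: ", paste(status, collapse = "\n"))
      }
    }
  )
  invisible(path)
}

#' Total-count normalize and log-transform expression
#'
#' Scales each cell so its total expression equals `target_sum`, then applies
#' `log(1 + x)`. Cells whose total is zero are left unscaled with a warning.
#' A second call on already-normalized data is refused with a warning, so the
#' transformation cannot be applied twice by accident.
#'
#' @param mat an [aem()] object holding non-negative raw counts.
#' @param target_sum per-cell total after scaling (default 10,000).
#' @return The normalized [aem()] object with `normalized = TRUE`.
#' @export
normalize_expression <- function(mat, target_sum = 1e4) {
  stopifnot(inherits(mat, "aem"), target_sum > 0)
  if (mat$normalized) {
    warning("data are already log-normalized; returning unchanged")
    return(mat)
  }
  if (any(mat$values < 0)) stop("negative expression values; expected raw counts")
  totals <- rowSums(mat$values)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) left unscaled")
    totals[zero] <- 1
  }
  scaled <- mat$values * (target_sum / totals)
  scaled[zero, ] <- 0
  mat$values <- log1p(scaled)
  mat$normalized <- TRUE
  mat
}

#' Select highly variable genes
#'
#' Keeps the `n_top` genes with the highest variance of (log-normalized)
#' expression across cells, ordered by descending score with ties broken by
#' gene name. The scoring rule is deliberately simple and deterministic;
#' substitute your own subset upstream if you prefer a dispersion-binned rule.
#'
#' @param mat an [aem()] object.
#' @param n_top number of genes to keep.
#' @return The [aem()] object restricted to the selected genes.
#' @export
select_hvg <- function(mat, n_top) {
  stopifnot(inherits(mat, "aem"), n_top >= 1)
  score <- apply(mat$values, 2L, stats::var)
  ord <- order(-score, gene_names(mat))
  if (n_top > ncol(mat$values)) {
    warning("n_top exceeds gene count; returning all genes")
    n_top <- ncol(mat$values)
  }
  keep <- ord[seq_len(n_top)]
  out <- mat
  out$values <- mat$values[, keep, drop = FALSE]
  out
}

#' Restrict to one control/perturbation pair
#'
#' Drops cells from any other condition and binary-codes the remaining
#' conditions (control = 0, perturbed = 1). Multi-condition datasets are
#' modelled one pair at a time.
#'
#' @param mat an [aem()] object.
#' @param control_label,perturbed_label condition labels present in `mat`.
#' @return The restricted [aem()] with `condition_codes` set.
#' @export
restrict_to_pair <- function(mat, control_label, perturbed_label) {
  stopifnot(inherits(mat, "aem"))
  present <- unique(mat$conditions)
  for (lab in c(control_label, perturbed_label)) {
    if (!lab %in% present) stop("condition label not found: ", lab)
  }
  keep <- mat$conditions %in% c(control_label, perturbed_label)
  out <- aem_subset(mat, keep)
  out$condition_codes <- ifelse(out$conditions == control_label, 0L, 1L)
  out$condition_levels <- c(control_label, perturbed_label)
  out
}

#' Hold out one cell type's perturbed cells
#'
#' Removes all (target cell type, perturbed) cells from the training data;
#' they become the evaluation ground truth. The target's control cells remain
#' in training and are also returned separately as the prediction input.
#'
#' @param mat an [aem()] object restricted to a binary condition pair.
#' @param target_cell_type the held-out cell type.
#' @return An object of class `holdout_split` with elements `train`,
#'   `target_control`, `heldout_truth`, `target_cell_type`,
#'   `perturbed_condition`.
#' @export
hold_out_target <- function(mat, target_cell_type) {
  stopifnot(inherits(mat, "aem"))
  codes <- condition_codes(mat)
  is_target <- mat$cell_types == target_cell_type
  if (!any(is_target & codes == 0L)) {
    stop("target cell type has no control cells: ", target_cell_type)
  }
  if (!any(is_target & codes == 1L)) {
    stop("target cell type has no perturbed cells: ", target_cell_type)
  }
  held <- is_target & codes == 1L
  split <- structure(
    list(
      train = aem_subset(mat, !held),
      target_control = aem_subset(mat, is_target & codes == 0L),
      heldout_truth = aem_subset(mat, held),
      target_cell_type = target_cell_type,
      perturbed_condition = mat$condition_levels[2L]
    ),
    class = "holdout_split"
  )
  message(sprintf(
    "hold-out '%s': %d train cells, %d target-control, %d held-out perturbed",
    target_cell_type, nrow(split$train$values),
    nrow(split$target_control$values), nrow(split$heldout_truth$values)
  ))
  split
}

#' @export
print.holdout_split <- function(x, ...) {
  cat(sprintf(
    "<holdout_split> target '%s': %d train / %d target-control / %d held-out\n",
    x$target_cell_type, nrow(x$train$values),
    nrow(x$target_control$values), nrow(x$heldout_truth$values)
  ))
  invisible(x)
}
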