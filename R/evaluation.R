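# Prediction of the held-out perturbation response and the two R-squared
# metrics: squared Pearson correlation of per-gene means over all genes and
# over the top differentially expressed genes.

#' Predict the perturbed state of control cells
#'
#' Embeds the target cells into the latent space with their control condition
#' code, decodes the condition-invariant part as-is, and maps the
#' condition-specific part through the projection layer with the perturbed
#' condition code inserted. The prediction is the sum of the two decoder
#' outputs. Posterior means are used (no sampling) for stability.
#'
#' @param model a trained [invae_init()] model.
#' @param target_control an [aem()] of control cells of one cell type, or a
#'   numeric matrix together with `c_code`.
#' @param c_code integer cell-type code; derived from the [aem()] when absent.
#' @return A cells x genes matrix of predicted perturbed expression.
#' @export
predict_perturbed <- function(model, target_control, c_code = NULL) {
  stopifnot(inherits(model, "invae_model"))
  if (inherits(target_control, "aem")) {
    codes <- condition_codes(target_control)
    if (any(codes != 0L)) {
      stop("predict_perturbed() expects control cells only")
    }
    if (length(unique(target_control$cell_types)) != 1L) {
      stop("predict_perturbed() expects a single cell type")
    }
    if (is.null(c_code)) {
      c_code <- cell_type_codes(target_control, model$cell_type_levels)[1L]
    }
    x <- target_control$values
  } else {
    if (is.null(c_code)) stop("c_code is required for matrix input")
    x <- as.matrix(target_control)
  }
  latent <- encode(model, x, c_codes = c_code, s_codes = 0, sample = FALSE)
  x_s <- decode_specific(model, project_latent(model, latent$mu_s, 1))
  pred <- if (model$mode == "full") {
    decode_invariant(model, latent$mu_c, c_code) + x_s
  } else {
    x_s
  }
  dimnames(pred) <- dimnames(x)
  pred
}

#' Squared Pearson correlation of per-gene means
#'
#' Computes the per-gene mean expression of each matrix and returns the
#' squared Pearson correlation between the two mean vectors -- the convention
#' used to score perturbation predictions in this literature. Note the metric
#' is invariant to affine maps of either mean vector (a perfectly
#' anticorrelated prediction also scores 1), so it measures the shape of the
#' mean profile, not its scale or sign.
#'
#' @param real,predicted numeric matrices over the same genes.
#' @return A scalar in \[0, 1\]; `NA` with a warning if either mean vector is
#'   constant.
#' @export
r_squared_means <- function(real, predicted) {
  stopifnot(ncol(real) == ncol(predicted))
  m_real <- colMeans(real)
  m_pred <- colMeans(predicted)
  if (stats::sd(m_real) == 0 || stats::sd(m_pred) == 0) {
    warning("constant mean vector; R-squared undefined")
    return(NA_real_)
  }
  min(stats::cor(m_real, m_pred)^2, 1)
}

#' Top differentially expressed genes between two conditions
#'
#' Ranks genes by the absolute standardized two-sample rank-sum (Wilcoxon)
#' statistic between real control and real perturbed cells, with the normal
#' approximation and tie correction; ties in the statistic are broken by gene
#' name. Predictions are never used for the ranking.
#'
#' @param control,perturbed numeric matrices over the same genes.
#' @param k number of genes to return (default 100).
#' @return Character vector of the top `k` gene names, in ranking order.
#' @export
top_degs <- function(control, perturbed, k = 100) {
  stopifnot(ncol(control) == ncol(perturbed), nrow(control) >= 1,
            nrow(perturbed) >= 1)
  genes <- colnames(control)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_len(ncol(control)))
  if (k > length(genes)) {
    warning("k exceeds gene count; returning all genes")
    k <- length(genes)
  }
  if (k == 0L) return(character(0))
  n1 <- nrow(perturbed)
  n2 <- nrow(control)
  n <- n1 + n2
  z <- vapply(seq_along(genes), function(j) {
    r <- rank(c(perturbed[, j], control[, j]))
    W <- sum(r[seq_len(n1)])
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(0)
    (W - n1 * (n + 1) / 2) / sqrt(sigma2)
  }, 1.0)
  ord <- order(-abs(z), genes)
  genes[ord[seq_len(k)]]
}

#' Score a predicted perturbation response against the held-out truth
#'
#' @param predicted cells x genes matrix of predicted perturbed expression.
#' @param split the [hold_out_target()] split providing `heldout_truth` (real
#'   perturbed cells) and `target_control` (used, with the truth, to define
#'   the DEG set).
#' @param k number of top DEGs for the focused metric.
#' @param metadata optional named list stored in the report.
#' @return An `evaluation_report`: `r2_all`, `r2_deg100`, `deg_list`,
#'   `n_predicted`, `target_cell_type`, per-gene mean vectors, and metadata.
#' @export
evaluate_prediction <- function(predicted, split, k = 100, metadata = list()) {
  stopifnot(inherits(split, "holdout_split"))
  truth <- split$heldout_truth$values
  stopifnot(ncol(predicted) == ncol(truth))
  degs <- top_degs(split$target_control$values, truth, k = k)
  r2_all <- r_squared_means(truth, predicted)
  r2_deg <- r_squared_means(truth[, degs, drop = FALSE],
                            predicted[, degs, drop = FALSE])
  structure(
    list(
      r2_all = r2_all, r2_deg100 = r2_deg, deg_list = degs,
      n_predicted = nrow(predicted),
      target_cell_type = split$target_cell_type,
      mean_real = colMeans(truth), mean_predicted = colMeans(predicted),
      k = k, metadata = metadata
    ),
    class = "evaluation_report"
  )
}

#' Predict and score the held-out perturbation response
#'
#' Runs [predict_perturbed()] on the split's target-control cells and scores
#' the result with [evaluate_prediction()].
#'
#' @param model a trained [invae_init()] model.
#' @param split a [hold_out_target()] split.
#' @param k number of top DEGs.
#' @return An `evaluation_report`.
#' @export
evaluate_holdout <- function(model, split, k = 100) {
  predicted <- predict_perturbed(model, split$target_control)
  evaluate_prediction(
    predicted, split, k = k,
    metadata = list(
      config_hash = rlang::hash(model$config), seed = model$config$seed,
      mode = model$mode
    )
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> target '%s': R2(all genes) = %.3f, R2(top-%d DEGs) = %.3f (%d cells)\n",
    x$target_cell_type, x$r2_all, x$k, x$r2_deg100, x$n_predicted
  ))
  invisible(x)
}

#' Per-gene means underlying an evaluation report
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return A tibble with per-gene real and predicted means and a DEG flag.
#' @export
tidy.evaluation_report <- function(x, ...) {
  genes <- names(x$mean_real)
  tibble::tibble(
    gene = genes, mean_real = unname(x$mean_real),
    mean_predicted = unname(x$mean_predicted),
    is_deg = genes %in% x$deg_list
  )
}

#' One-row summary of an evaluation report
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    target_cell_type = x$target_cell_type, r2_all = x$r2_all,
    r2_deg100 = x$r2_deg100, k = x$k, n_predicted = x$n_predicted
  )
}

#' Mean-vs-mean scatter plot of an evaluation report
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return A ggplot object: predicted vs real per-gene means, DEGs
#'   highlighted.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()")
  }
  df <- tidy.evaluation_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_real,
                                   y = .data$mean_predicted,
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "real per-gene mean", y = "predicted per-gene mean",
      colour = sprintf("top-%d DEG", object$k),
      title = sprintf("R2 all = %.3f, R2 DEG = %.3f",
                      object$r2_all, object$r2_deg100)
    ) +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report
#'
#' Reports round-trip through JSON losslessly (numeric values at full
#' precision).
#'
#' @param report an `evaluation_report`.
#' @param path JSON file.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- unclass(report)
  # keep gene names: named atomic vectors would serialize as bare arrays
  payload$mean_real <- as.list(payload$mean_real)
  payload$mean_predicted <- as.list(payload$mean_predicted)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$mean_real <- unlist(payload$mean_real)
  payload$mean_predicted <- unlist(payload$mean_predicted)
  payload$metadata <- as.list(payload$metadata)
  structure(payload, class = "evaluation_report")
}

#' Export the two decoded spaces of a dataset
#'
#' Decodes every cell's condition-invariant part through decoder 1 and its
#' projected condition-specific part through decoder 2 (using the cell's own
#' condition code), returning both as annotated matrices for external
#' embedding or plotting. Their sum equals the model reconstruction.
#'
#' With `sample = TRUE` the latent codes are drawn from the posterior instead
#' of using its mean, so the decoded matrices are generative samples whose
#' within-group spread reflects the model's stochasticity; use this when
#' comparing group-separation statistics against raw (noisy) data, where
#' deterministic mean-decodings would have degenerate within-group variance.
#'
#' @param model a trained [invae_init()] model.
#' @param mat an [aem()] restricted to a binary condition pair.
#' @param sample decode sampled latent codes instead of posterior means.
#' @return A list of two [aem()] objects, `invariant` and `specific`.
#' @export
export_decoded_spaces <- function(model, mat, sample = FALSE) {
  stopifnot(inherits(model, "invae_model"), inherits(mat, "aem"))
  rec <- reconstruct(model, mat, sample = sample)
  out_inv <- mat
  out_inv$values <- rec$x_c
  dimnames(out_inv$values) <- dimnames(mat$values)
  out_spec <- mat
  out_spec$values <- rec$x_s
  dimnames(out_spec$values) <- dimnames(mat$values)
  list(invariant = out_inv, specific = out_spec)
}
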