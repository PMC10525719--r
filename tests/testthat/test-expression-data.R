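# Loading, preprocessing and hold-out splitting of annotated matrices.

make_counts <- function() {
  set.seed(3)
  values <- matrix(rpois(10 * 5, 8), 10, 5,
                   dimnames = list(sprintf("c%02d", 1:10),
                                   sprintf("g%d", 1:5)))
  aem(values,
      cell_types = rep(c("A", "B"), each = 5),
      conditions = rep(c("ctl", "stim"), 5))
}

test_that("csv round trip preserves values and labels", {
  mat <- make_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(mat, path, "csv")
  back <- load_dataset(path, "csv")
  expect_equal(back$values, mat$values, tolerance = 1e-6)
  expect_identical(back$cell_types, mat$cell_types)
  expect_identical(back$conditions, mat$conditions)
  expect_identical(colnames(back$values), colnames(mat$values))
})

test_that("mtx round trip matches an independently parsed triplet file", {
  mat <- make_counts()
  dir <- withr::local_tempdir()
  write_dataset(mat, dir, "mtx")
  back <- load_dataset(dir, "mtx")
  expect_equal(back$values, mat$values, tolerance = 1e-6)
  expect_identical(back$cell_types, mat$cell_types)

  # independent parse of the MatrixMarket triplets (genes x cells)
  lines <- readLines(file.path(dir, "matrix.mtx"))
  lines <- lines[!startsWith(lines, "%")]
  dims <- scan(text = lines[1], quiet = TRUE)
  trip <- read.table(text = lines[-1])
  dense <- matrix(0, dims[1], dims[2])
  dense[cbind(trip$V1, trip$V2)] <- trip$V3
  expect_equal(unname(t(dense)), unname(mat$values))
})

test_that("h5ad round trip preserves values and labels", {
  mat <- make_counts()
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_dataset(mat, path, "h5ad")
  back <- load_dataset(path, "h5ad")
  expect_equal(back$values, mat$values, tolerance = 1e-6)
  expect_identical(back$cell_types, mat$cell_types)
  expect_identical(back$conditions, mat$conditions)
})

test_that("missing annotation columns and non-numeric values are rejected", {
  mat <- make_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(mat, path, "csv", condition_col = "stimulus")
  expect_error(load_dataset(path, "csv"), "annotation column 'condition'")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,cell_type,condition,g1", "c1,A,ctl,x"), bad)
  expect_error(load_dataset(bad, "csv"), "non-numeric")

  expect_error(load_dataset("does-not-exist.csv"), "not found")
})

test_that("normalization scales to target sum then log-transforms", {
  mat <- aem(matrix(c(2, 2, 0), 1, 3), "A", "ctl")
  out <- normalize_expression(mat, target_sum = 4)
  expect_equal(unname(out$values[1, ]), c(log(3), log(3), 0))
  expect_true(out$normalized)

  # already-normalized data are refused, unchanged
  expect_warning(again <- normalize_expression(out, 4), "already")
  expect_identical(again$values, out$values)

  zero <- aem(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE), c("A", "A"),
              c("ctl", "ctl"))
  expect_warning(nz <- normalize_expression(zero, 10), "all-zero")
  expect_equal(unname(nz$values[2, ]), c(0, 0))

  neg <- aem(matrix(c(-1, 2), 1, 2), "A", "ctl")
  expect_error(normalize_expression(neg), "negative")
})

test_that("highly variable gene selection ranks by variance", {
  set.seed(4)
  n <- 40
  values <- cbind(
    g_big = rnorm(n, 5, sqrt(5)),
    g_small = rnorm(n, 5, sqrt(0.1)),
    g_mid = rnorm(n, 5, sqrt(2)),
    g_const = rep(2, n)
  )
  mat <- aem(pmax(values, 0), rep("A", n), rep("ctl", n), normalized = TRUE)
  top2 <- select_hvg(mat, 2)
  expect_identical(colnames(top2$values), c("g_big", "g_mid"))

  all4 <- select_hvg(mat, 4)
  expect_setequal(colnames(all4$values), colnames(values))
  expect_identical(colnames(all4$values)[4], "g_const")

  expect_warning(more <- select_hvg(mat, 10), "exceeds")
  expect_equal(ncol(more$values), 4)
})

test_that("restrict_to_pair drops other conditions and binary-codes the pair", {
  set.seed(5)
  values <- matrix(runif(12 * 3), 12, 3)
  mat <- aem(values, rep("A", 12),
             rep(c("healthy", "hpoly", "salmonella"), each = 4))
  out <- restrict_to_pair(mat, "healthy", "hpoly")
  expect_equal(nrow(out$values), 8)
  expect_setequal(unique(out$conditions), c("healthy", "hpoly"))
  expect_identical(out$condition_codes, rep(c(0L, 1L), each = 4))

  # already-binary input: identity up to recoding
  again <- restrict_to_pair(out, "healthy", "hpoly")
  expect_identical(again$values, out$values)
  expect_identical(again$condition_codes, out$condition_codes)

  expect_error(restrict_to_pair(mat, "healthy", "listeria"), "not found")
})

test_that("hold_out_target removes exactly the target perturbed cells", {
  cfg <- synthetic_config(n_cell_types = 4, n_genes = 6, cells_per_group = 10,
                          noise_sd = 0.1, seed = 9)
  mat <- restrict_to_pair(generate_synthetic(cfg)$data, "control", "perturbed")
  split <- suppressMessages(hold_out_target(mat, "type_2"))

  expect_equal(nrow(split$train$values), 70)
  expect_equal(nrow(split$heldout_truth$values), 10)
  expect_equal(nrow(split$target_control$values), 10)

  # no (target, perturbed) cell remains in training
  expect_false(any(split$train$cell_types == "type_2" &
                     split$train$condition_codes == 1L))
  # all target control cells are in training
  expect_true(all(rownames(split$target_control$values) %in%
                    rownames(split$train$values)))
  # re-merging restores the original cell id multiset
  expect_setequal(
    c(rownames(split$train$values), rownames(split$heldout_truth$values)),
    rownames(mat$values)
  )

  # a target without perturbed cells is rejected
  only_ctl <- restrict_to_pair(
    aem(mat$values, ifelse(mat$condition_codes == 1L & mat$cell_types == "type_3",
                           "type_4", mat$cell_types),
        mat$conditions),
    "control", "perturbed"
  )
  expect_error(suppressMessages(hold_out_target(only_ctl, "type_3")),
               "no perturbed")
})
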