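# Metrics and prediction plumbing: squared-correlation contracts, DEG
# ranking, report round trips, decoded-space consistency.

test_that("r_squared_means follows the squared-Pearson contract", {
  mk <- function(means) rbind(means, means)  # two identical cells per gene
  expect_equal(r_squared_means(mk(c(1, 2, 3)), mk(c(1, 2, 3))), 1)
  expect_equal(r_squared_means(mk(c(1, 2, 3)), mk(c(1, 3, 2))), 0.25)
  # documented caveat: the metric ignores the sign of the association
  expect_equal(r_squared_means(mk(c(1, 2, 3)), mk(c(3, 2, 1))), 1)
  expect_warning(na <- r_squared_means(mk(c(2, 2, 2)), mk(c(1, 2, 3))),
                 "constant")
  expect_true(is.na(na))
})

test_that("top_degs ranks truly responding genes first", {
  set.seed(41)
  G <- 30
  n <- 60
  genes <- sprintf("g%02d", seq_len(G))
  ctl <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, genes))
  prt <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, genes))
  prt[, 1:10] <- prt[, 1:10] + 3
  expect_setequal(top_degs(ctl, prt, k = 10), genes[1:10])

  # identical inputs: all statistics zero, deterministic name ordering
  expect_identical(top_degs(ctl, ctl, k = 5), genes[1:5])
  expect_identical(top_degs(ctl, prt, k = 0), character(0))
  expect_warning(all_g <- top_degs(ctl, prt, k = 100), "exceeds")
  expect_equal(length(all_g), G)
})

test_that("a perfect oracle predictor scores 1 on both metrics", {
  split <- tiny_split()
  rep <- evaluate_prediction(split$heldout_truth$values, split, k = 5)
  expect_equal(rep$r2_all, 1)
  expect_equal(rep$r2_deg100, 1)
  expect_equal(length(rep$deg_list), 5)
  expect_equal(rep$target_cell_type, "type_1")

  td <- tidy(rep)
  expect_equal(sum(td$is_deg), 5)
  expect_equal(nrow(td), ncol(split$heldout_truth$values))
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("evaluation reports round-trip through JSON losslessly", {
  split <- tiny_split()
  rep <- evaluate_prediction(split$heldout_truth$values, split, k = 4,
                             metadata = list(seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$r2_all, rep$r2_all)
  expect_equal(back$r2_deg100, rep$r2_deg100)
  expect_identical(back$deg_list, rep$deg_list)
  expect_equal(back$mean_real, rep$mean_real)
  expect_equal(back$metadata$seed, 7)
})

test_that("predict_perturbed validates its input and matches shapes", {
  mc <- tiny_config()
  split <- tiny_split()
  model <- invae_init(mc, unique(split$train$cell_types))
  pred <- predict_perturbed(model, split$target_control)
  expect_equal(dim(pred), dim(split$target_control$values))
  expect_true(all(is.finite(pred)))

  mixed <- split$train
  expect_error(predict_perturbed(model, mixed), "control cells only|single cell type")
  expect_error(predict_perturbed(model, split$target_control$values),
               "c_code")
})

test_that("decoded spaces sum to the reconstruction and keep annotations", {
  mc <- tiny_config()
  mat <- tiny_dataset()
  model <- invae_init(mc, unique(mat$cell_types))
  spaces <- export_decoded_spaces(model, mat)
  rec <- reconstruct(model, mat)
  expect_equal(spaces$invariant$values + spaces$specific$values, rec$x_hat)
  expect_identical(spaces$specific$cell_types, mat$cell_types)
  expect_identical(dimnames(spaces$invariant$values), dimnames(mat$values))

  # sampled decodings differ from mean decodings but keep shapes
  set.seed(5)
  sampled <- export_decoded_spaces(model, mat, sample = TRUE)
  expect_equal(dim(sampled$specific$values), dim(mat$values))
  expect_false(identical(sampled$specific$values, spaces$specific$values))
})
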