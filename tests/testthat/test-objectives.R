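# Loss terms: reconstruction contracts, the KL decomposition against its
# naive oracle, ANOVA statistics, navigation-loss assembly, composition.

test_that("reconstruction loss follows the masked MSE contract", {
  x <- matrix(c(0, 0), 1, 2)
  x_hat <- matrix(c(1, 1), 1, 2)
  expect_equal(reconstruction_loss(x_hat, x), 1)
  expect_equal(reconstruction_loss(x, x), 0)

  x2 <- rbind(x, x + 2)
  xh2 <- rbind(x_hat, x + 2)
  expect_equal(reconstruction_loss(xh2, x2, cell_mask = c(TRUE, FALSE)), 1)
  expect_equal(reconstruction_loss(xh2, x2), 0.5)
  expect_warning(z <- reconstruction_loss(xh2, x2, cell_mask = integer(0)),
                 "empty")
  expect_equal(z, 0)
})

test_that("a posterior frozen at the prior has zero MI, TC and dimension-wise KL", {
  set.seed(21)
  M <- 10
  D <- 4
  mu <- matrix(0, M, D)
  lv <- matrix(0, M, D)
  z <- matrix(rnorm(M * D), M, D)
  out <- kl_decomposition(list(z = z, mu = mu, logvar = lv), dataset_size = 50)
  expect_equal(out$mi, 0, tolerance = 1e-10)
  expect_equal(out$tc, 0, tolerance = 1e-10)
  expect_equal(out$dwkl, 0, tolerance = 1e-10)
})

test_that("the minibatch KL estimator matches the naive double-loop oracle", {
  set.seed(22)
  for (trial in 1:4) {
    M <- sample(3:12, 1)
    D <- sample(1:4, 1)
    N <- M + sample(0:40, 1)
    mu <- matrix(rnorm(M * D), M, D)
    lv <- matrix(rnorm(M * D, 0, 0.5), M, D)
    z <- mu + exp(0.5 * lv) * matrix(rnorm(M * D), M, D)
    mine <- kl_decomposition(list(z = z, mu = mu, logvar = lv), N)
    ref <- kl_naive(z, mu, lv, N)
    expect_equal(mine$mi, ref$mi, tolerance = 1e-8)
    expect_equal(mine$tc, ref$tc, tolerance = 1e-8)
    expect_equal(mine$dwkl, ref$dwkl, tolerance = 1e-8)
  }
})

test_that("total correlation of a single latent dimension is zero", {
  set.seed(23)
  mu <- matrix(rnorm(8), 8, 1)
  lv <- matrix(rnorm(8, 0, 0.3), 8, 1)
  z <- mu + exp(0.5 * lv) * matrix(rnorm(8), 8, 1)
  out <- kl_decomposition(list(z = z, mu = mu, logvar = lv), 30)
  expect_equal(out$tc, 0, tolerance = 1e-12)
})

test_that("kl_decomposition rejects a batch of one cell", {
  expect_error(
    kl_decomposition(list(z = matrix(0, 1, 2), mu = matrix(0, 1, 2),
                          logvar = matrix(0, 1, 2)), 10),
    "at least 2"
  )
})

test_that("anova_f reproduces the textbook statistic and its edge cases", {
  # hand-computable case: groups [0,1] vs [2,3] give F = 8 in one dimension
  expect_equal(anova_f(list(c(0, 1), c(2, 3)))$F, 8)

  # equal group means: zero between-group sum of squares, zero loss
  expect_equal(anova_f(list(c(0, 2), c(1, 1)))$loss, 0)

  # a single usable group degenerates to zero with a warning
  expect_warning(one <- anova_f(list(matrix(rnorm(6), 3))), "fewer than 2")
  expect_equal(one$loss, 0)
  expect_warning(drop <- anova_f(list(c(1, 2), c(5), c(3, 4))), "dropped")
  expect_gt(drop$loss, 0)
  w <- capture_warnings(both <- anova_f(list(c(1, 2), c(5))))
  expect_length(w, 2)
  expect_equal(both$loss, 0)
})

test_that("navigation losses match hand-assembled group statistics", {
  mc <- tiny_config(anova_epsilon = 1e-8)
  mat <- tiny_dataset()
  model <- invae_init(mc, unique(mat$cell_types))
  nav <- navigation_losses(model, mat)
  expect_true(all(is.finite(c(nav$ano_zc, nav$ano_zs_control, nav$ano_zp))))

  enc <- encode(model, mat)
  cc <- mat$cell_types
  ss <- mat$condition_codes

  # ano_zc by hand: per type, invariant codes grouped by condition
  zc_hand <- sum(vapply(unique(cc), function(ty) {
    anova_f(list(enc$z_c[cc == ty & ss == 0, ], enc$z_c[cc == ty & ss == 1, ]),
            epsilon = mc$anova_epsilon)$loss
  }, 1.0))
  expect_equal(nav$ano_zc, zc_hand, tolerance = 1e-12)

  # ano_zs_control by hand: control cells grouped by cell type
  ctl_groups <- lapply(sort(unique(cc)), function(ty) {
    enc$z_s[cc == ty & ss == 0, ]
  })
  expect_equal(nav$ano_zs_control,
               anova_f(ctl_groups, epsilon = mc$anova_epsilon)$loss,
               tolerance = 1e-12)

  # ano_zp by hand from the projection consistency sets D1/D2
  zp_hand <- 0
  for (ty in sort(unique(cc))) {
    z1 <- enc$z_s[cc == ty & ss == 0, ]
    z2 <- enc$z_s[cc == ty & ss == 1, ]
    for (s_ins in 0:1) {
      zp_hand <- zp_hand + anova_f(
        list(project_latent(model, z1, s_ins),
             project_latent(model, z2, s_ins)),
        epsilon = mc$anova_epsilon
      )$loss
    }
  }
  expect_equal(nav$ano_zp, zp_hand, tolerance = 1e-12)

  # the returned projection groups are exactly the D1/D2 members
  g <- nav$groups[[1]]
  expect_named(g, c("D1", "D2"))
  ty1 <- sort(unique(cc))[1]
  expect_equal(g$D1[[1]],
               project_latent(model, enc$z_s[cc == ty1 & ss == 0, ], 0))
})

test_that("degenerate batches zero the affected navigation terms with warnings", {
  mc <- tiny_config()
  mat <- tiny_dataset()
  model <- invae_init(mc, unique(mat$cell_types))

  inv <- asNamespace("invae")
  one_type <- inv$aem_subset(mat, mat$cell_types == "type_1")
  w <- capture_warnings(nav <- navigation_losses(model, one_type))
  expect_true(any(grepl("ano_zs_control", w)))
  expect_equal(nav$ano_zs_control, 0)

  all_ctl <- inv$aem_subset(mat, mat$condition_codes == 0L)
  w2 <- capture_warnings(nav2 <- navigation_losses(model, all_ctl))
  expect_equal(nav2$ano_zc, 0)
  expect_equal(nav2$ano_zp, 0)
})

test_that("total loss composes its parts with the configured weights", {
  mc <- tiny_config(recon_weight = 1)
  parts <- list(recon_other = 1.5, recon_target = 0.25, mi = 0.1, tc = 0.2,
                dwkl = 0.3, ano_zc = 2, ano_zs_control = 3, ano_zp = 4)
  base <- total_loss(parts, include_target_recon = FALSE, config = mc)
  expect_equal(base$total, 1.5 + 0.1 + mc$beta * 0.2 + 0.3 + 2 + 3 + 4)

  with_target <- total_loss(parts, include_target_recon = TRUE, config = mc)
  expect_equal(with_target$total - base$total, parts$recon_target)

  mc0 <- tiny_config(beta = 0, recon_weight = 1)
  no_tc <- total_loss(parts, FALSE, mc0)
  expect_equal(no_tc$total, base$total - mc$beta * 0.2)

  # likelihood-scale weighting multiplies only the reconstruction terms
  mc10 <- tiny_config(recon_weight = 10)
  scaled <- total_loss(parts, TRUE, mc10)
  expect_equal(scaled$total,
               10 * (1.5 + 0.25) + 0.1 + mc$beta * 0.2 + 0.3 + 2 + 3 + 4)

  expect_error(total_loss(parts[-1], FALSE, mc), "missing loss parts")
  expect_s3_class(tidy(base), "tbl_df")
})
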