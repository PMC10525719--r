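# Reverse-mode engine: gradients of composite graphs against central
# differences, and the analytic properties the ANOVA loss must satisfy.

ag <- asNamespace("invae")

test_that("backward pass matches finite differences through an MLP block", {
  set.seed(11)
  X <- matrix(rnorm(5 * 4), 5, 4)
  W1 <- matrix(rnorm(4 * 6, 0, 0.5), 4, 6)
  b1 <- matrix(rnorm(6, 0, 0.1), 1, 6)
  W2 <- matrix(rnorm(6 * 3, 0, 0.5), 6, 3)

  loss_fn <- function(W1v, b1v, W2v) {
    h <- pmax(sweep(X %*% W1v, 2, -as.vector(b1v), "-"), 0)
    mean((h %*% W2v)^2)
  }
  tape <- ag$ag_tape()
  nW1 <- ag$ag_leaf(tape, W1)
  nb1 <- ag$ag_leaf(tape, b1)
  nW2 <- ag$ag_leaf(tape, W2)
  h <- ag$ag_relu(tape, ag$ag_add(tape, ag$ag_matmul(tape, X, nW1), nb1))
  out <- ag$ag_mean(tape, ag$ag_square(tape, ag$ag_matmul(tape, h, nW2)))
  expect_equal(as.numeric(out$value), loss_fn(W1, b1, W2))

  ag$ag_backward(tape, out)
  expect_equal(nW1$grad, numeric_grad(function(w) loss_fn(w, b1, W2), W1),
               tolerance = 1e-6)
  expect_equal(nb1$grad, numeric_grad(function(b) loss_fn(W1, b, W2), b1),
               tolerance = 1e-6)
  expect_equal(nW2$grad, numeric_grad(function(w) loss_fn(W1, b1, w), W2),
               tolerance = 1e-6)
})

test_that("slicing, concatenation and reductions propagate exact gradients", {
  set.seed(12)
  A <- matrix(rnorm(6 * 4), 6, 4)
  f <- function(Av) {
    top <- Av[1:3, , drop = FALSE]
    joined <- cbind(top, top * top)
    cm <- colMeans(joined)
    sum(exp(cm / 4))
  }
  tape <- ag$ag_tape()
  nA <- ag$ag_leaf(tape, A)
  top <- ag$ag_rows(tape, nA, 1:3)
  joined <- ag$ag_cbind(tape, top, ag$ag_square(tape, top))
  cm <- ag$ag_colmeans(tape, joined)
  out <- ag$ag_sum(tape, ag$ag_exp(tape, ag$ag_scale(tape, cm, 1 / 4)))
  expect_equal(as.numeric(out$value), f(A))
  ag$ag_backward(tape, out)
  expect_equal(nA$grad, numeric_grad(f, A), tolerance = 1e-6)
})

test_that("ANOVA loss gradient matches finite differences and vanishes at equal means", {
  set.seed(13)
  g1 <- matrix(rnorm(4 * 2), 4, 2)
  g2 <- matrix(rnorm(5 * 2), 5, 2)
  f <- function(g1v) {
    anova_f(list(g1v, g2), epsilon = 0)$loss
  }
  tape <- ag$ag_tape()
  n1 <- ag$ag_leaf(tape, g1)
  out <- ag$anova_f_ag(tape, list(n1, g2), epsilon = 0)$loss
  ag$ag_backward(tape, out)
  expect_equal(n1$grad, numeric_grad(f, g1), tolerance = 1e-5)

  # translate both groups onto identical means: gradient w.r.t. values is 0
  m <- colMeans(rbind(g1, g2))
  e1 <- sweep(g1, 2, colMeans(g1), "-") + rep(1, 4) %o% m
  e2 <- sweep(g2, 2, colMeans(g2), "-") + rep(1, 5) %o% m
  tape2 <- ag$ag_tape()
  ne1 <- ag$ag_leaf(tape2, e1)
  ne2 <- ag$ag_leaf(tape2, e2)
  out2 <- ag$anova_f_ag(tape2, list(ne1, ne2), epsilon = 0)$loss
  expect_equal(as.numeric(out2$value), 0, tolerance = 1e-24)
  ag$ag_backward(tape2, out2)
  expect_lt(max(abs(ne1$grad)), 1e-10)
  expect_lt(max(abs(ne2$grad)), 1e-10)
})

test_that("KL kernel gradients match finite differences", {
  set.seed(14)
  M <- 6
  D <- 3
  N <- 25
  mu <- matrix(rnorm(M * D), M, D)
  lv <- matrix(rnorm(M * D, 0, 0.3), M, D)
  z <- mu + exp(0.5 * lv) * matrix(rnorm(M * D), M, D)
  w <- c(0.7, 1.3, 0.4)
  f <- function(zv, muv, lvv) {
    r <- ag$kl_mws_forward_cpp(zv, muv, lvv, N)
    w[1] * r$mi + w[2] * r$tc + w[3] * r$dwkl
  }
  bk <- ag$kl_mws_backward_cpp(z, mu, lv, N, w[1], w[2], w[3])
  expect_equal(bk$gz, numeric_grad(function(x) f(x, mu, lv), z),
               tolerance = 1e-5)
  expect_equal(bk$gmu, numeric_grad(function(x) f(z, x, lv), mu),
               tolerance = 1e-5)
  expect_equal(bk$glogvar, numeric_grad(function(x) f(z, mu, x), lv),
               tolerance = 1e-5)
})

test_that("translating one group away from the grand mean increases the ANOVA loss", {
  set.seed(15)
  g1 <- matrix(rnorm(6), 6, 1)
  g2 <- matrix(rnorm(6), 6, 1)
  base <- anova_f(list(g1, g2), epsilon = 0)$loss
  shifts <- c(0.5, 1, 2, 4)
  dir <- sign(mean(g1) - mean(c(g1, g2)))
  if (dir == 0) dir <- 1
  losses <- vapply(shifts, function(s) {
    anova_f(list(g1 + s * dir, g2), epsilon = 0)$loss
  }, 1.0)
  expect_true(all(diff(c(base, losses)) > 0))
})
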