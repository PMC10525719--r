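# Loss terms: masked reconstruction, the total-correlation KL decomposition,
# the differentiable one-way ANOVA statistic, and the navigation losses that
# steer condition-invariant and condition-specific information into the two
# latent parts.

#' Masked mean-squared reconstruction loss
#'
#' Mean squared error between reconstruction and input over the selected
#' cells and all genes. An empty selection contributes 0 (with a warning), so
#' batches without target cells are handled gracefully.
#'
#' @param x_hat,x numeric matrices of identical shape.
#' @param cell_mask logical or integer row selection; `NULL` selects all.
#' @return A scalar.
#' @export
reconstruction_loss <- function(x_hat, x, cell_mask = NULL) {
  stopifnot(all(dim(x_hat) == dim(x)))
  if (is.null(cell_mask)) cell_mask <- seq_len(nrow(x))
  if (is.logical(cell_mask)) cell_mask <- which(cell_mask)
  if (length(cell_mask) == 0L) {
    warning("empty cell mask; reconstruction loss is 0")
    return(0)
  }
  d <- x_hat[cell_mask, , drop = FALSE] - x[cell_mask, , drop = FALSE]
  mean(d * d)
}

recon_loss_ag <- function(tape, x_hat, x, rows) {
  ag_mean(tape, ag_square(tape, ag_sub(
    tape, ag_rows(tape, x_hat, rows), x[rows, , drop = FALSE]
  )))
}

#' Minibatch estimate of the KL decomposition
#'
#' Estimates the three terms of the decomposition
#' `KL(q(z|x) || p(z)) = MI + TC + dimension-wise KL` over a batch using
#' weighted sampling from the aggregated posterior: the log marginal
#' `log q(z_i)` is approximated from the batch's posterior components, with a
#' sample's own component weighted `1/N` and every other component weighted
#' `(N-1)/(N (M-1))` for dataset size `N` and batch size `M`. The index-code
#' mutual information (MI), total correlation (TC) and dimension-wise KL sum
#' to the estimator's KL divergence by construction.
#'
#' @param latent either the list returned by [encode()] or a list with
#'   matrices `z`, `mu`, `logvar` (cells x latent dims, the concatenated
#'   latent).
#' @param dataset_size number of cells in the full training set.
#' @return A list with scalars `mi`, `tc`, `dwkl`.
#' @export
kl_decomposition <- function(latent, dataset_size) {
  z <- as.matrix(latent$z)
  mu <- as.matrix(latent$mu)
  lv <- as.matrix(latent$logvar)
  if (nrow(z) < 2L) stop("KL decomposition needs a batch of at least 2 cells")
  stopifnot(all(dim(z) == dim(mu)), all(dim(z) == dim(lv)),
            dataset_size >= nrow(z))
  out <- kl_mws_forward_cpp(z, mu, lv, as.numeric(dataset_size))
  list(mi = out$mi, tc = out$tc, dwkl = out$dwkl)
}

# Single fused autodiff node for mi + beta * tc + dwkl. The gradients are
# linear in the three term weights, so the fused kernel computes them once
# at weights (1, beta, 1) and the backward closure rescales by the scalar
# upstream gradient.
kl_node_ag <- function(tape, z, mu, lv, dataset_size, beta) {
  zv <- ag_value(z); muv <- ag_value(mu); lvv <- ag_value(lv)
  fwd <- kl_mws_fused_cpp(zv, muv, lvv, dataset_size, 1, beta, 1)
  val <- matrix(fwd$mi + beta * fwd$tc + fwd$dwkl, 1L, 1L)
  node <- ag_custom(tape, val, list(z, mu, lv), function(g) {
    gs <- as.numeric(g)
    list(gs * fwd$gz, gs * fwd$gmu, gs * fwd$glogvar)
  })
  node$parts <- fwd[c("mi", "tc", "dwkl")]
  node
}

anova_f_ag <- function(tape, groups, epsilon) {
  ns <- vapply(groups, function(g) nrow(ag_value(g)), 1L)
  n <- sum(ns)
  K <- length(groups)
  D <- ncol(ag_value(groups[[1L]]))
  means <- lapply(groups, function(g) ag_colmeans(tape, g))
  grand <- NULL
  for (k in seq_len(K)) {
    part <- ag_scale(tape, means[[k]], ns[k] / n)
    grand <- if (is.null(grand)) part else ag_add(tape, grand, part)
  }
  ssb <- NULL
  ssw <- NULL
  for (k in seq_len(K)) {
    db <- ag_scale(tape, ag_square(tape, ag_sub(tape, means[[k]], grand)), ns[k])
    ssb <- if (is.null(ssb)) db else ag_add(tape, ssb, db)
    dw <- ag_colsums(tape, ag_square(tape, ag_sub(tape, groups[[k]], means[[k]])))
    ssw <- if (is.null(ssw)) dw else ag_add(tape, ssw, dw)
  }
  msb <- ag_scale(tape, ssb, 1 / (K - 1))
  msw <- ag_add(tape, ag_scale(tape, ssw, 1 / (n - K)),
                matrix(epsilon, 1L, D))
  f_vec <- ag_div(tape, msb, msw)
  list(F = f_vec, loss = ag_mean(tape, f_vec))
}

#' Differentiable one-way ANOVA F statistic over latent dimensions
#'
#' For each latent dimension the classical one-way ANOVA F statistic
#' `F = (SS_between / df_between) / (SS_within / df_within + epsilon)` is
#' computed across the groups; the loss is the mean of the per-dimension
#' statistics. Low values indicate the groups share a distribution, which is
#' what the navigation losses minimize. Groups with fewer than 2 members are
#' dropped (the statistic is undefined for them); if fewer than 2 usable
#' groups remain, the loss is 0 with a warning.
#'
#' @param groups list of numeric matrices (members x dimensions) or vectors.
#' @param epsilon additive stabilizer on the within-group mean square. Use 0
#'   to reproduce the textbook statistic.
#' @return A list with `F` (per-dimension statistic) and `loss` (their mean).
#' @export
anova_f <- function(groups, epsilon = 0) {
  groups <- lapply(groups, function(g) {
    g <- if (is.matrix(g)) g else matrix(g, ncol = 1L)
    storage.mode(g) <- "double"
    g
  })
  sizes <- vapply(groups, nrow, 1L)
  if (any(sizes < 2L)) {
    warning(sum(sizes < 2L), " group(s) with fewer than 2 members dropped")
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) {
    warning("fewer than 2 usable groups; ANOVA loss is 0")
    D <- if (length(groups) >= 1L) ncol(groups[[1L]]) else 1L
    return(list(F = numeric(D), loss = 0))
  }
  D <- unique(vapply(groups, ncol, 1L))
  if (length(D) != 1L) stop("groups must share the same number of dimensions")
  out <- anova_f_ag(NULL, groups, epsilon)
  list(F = as.vector(ag_value(out$F)), loss = as.numeric(ag_value(out$loss)))
}

# The three navigation terms on an encoded batch. Returns autodiff nodes (or
# NULL when a term has no usable groups) plus, optionally, the projection
# group values that define the consistency sets D1/D2.
nav_terms_ag <- function(tape, P, enc, c_codes, s_codes, config, mode,
                         training = FALSE, collect_groups = FALSE) {
  eps <- config$anova_epsilon
  types <- sort(unique(c_codes))
  add <- function(acc, nd) if (is.null(acc)) nd else ag_add(tape, acc, nd)

  ano_zc <- NULL
  if (mode == "full") {
    for (t in types) {
      i0 <- which(c_codes == t & s_codes == 0)
      i1 <- which(c_codes == t & s_codes == 1)
      if (length(i0) >= 2L && length(i1) >= 2L) {
        grp <- list(ag_rows(tape, enc$z_c, i0), ag_rows(tape, enc$z_c, i1))
        ano_zc <- add(ano_zc, anova_f_ag(tape, grp, eps)$loss)
      }
    }
  }

  ctrl_groups <- list()
  for (t in types) {
    ic <- which(c_codes == t & s_codes == 0)
    if (length(ic) >= 2L) {
      ctrl_groups[[length(ctrl_groups) + 1L]] <- ag_rows(tape, enc$z_s, ic)
    }
  }
  ano_zs <- if (length(ctrl_groups) >= 2L) {
    anova_f_ag(tape, ctrl_groups, eps)$loss
  }

  ano_zp <- NULL
  groups <- list()
  for (t in types) {
    i0 <- which(c_codes == t & s_codes == 0)
    i1 <- which(c_codes == t & s_codes == 1)
    if (length(i0) < 2L || length(i1) < 2L) next
    z1 <- ag_rows(tape, enc$z_s, i0)
    z2 <- ag_rows(tape, enc$z_s, i1)
    d_sets <- list()
    for (s_ins in 0:1) {
      p1 <- project_fwd(tape, P, z1, s_ins, config, training)
      p2 <- project_fwd(tape, P, z2, s_ins, config, training)
      ano_zp <- add(ano_zp, anova_f_ag(tape, list(p1, p2), eps)$loss)
      if (collect_groups) {
        d_sets[[paste0("D", s_ins + 1L)]] <-
          list(ag_value(p1), ag_value(p2))
      }
    }
    if (collect_groups) groups[[paste0("type_code_", t)]] <- d_sets
  }
  list(ano_zc = ano_zc, ano_zs_control = ano_zs, ano_zp = ano_zp,
       groups = groups)
}

#' ANOVA navigation losses of a batch
#'
#' Evaluates the three navigation terms on an annotated batch (evaluation
#' mode, posterior means unless `sample = TRUE`):
#' \describe{
#'   \item{ano_zc}{per cell type, the ANOVA F of the condition-invariant codes
#'     grouped by condition, summed over cell types -- small when the
#'     invariant part ignores the perturbation.}
#'   \item{ano_zs_control}{the ANOVA F of the condition-specific codes of
#'     control cells grouped by cell type -- small when the control
#'     (homogeneous) space is shared across cell types.}
#'   \item{ano_zp}{per cell type and inserted condition, the ANOVA F between
#'     the projections of control-derived and perturbed-derived codes -- small
#'     when the projection layer maps both onto the same conditional space.}
#' }
#' Terms whose grouping is degenerate in the batch (for example a single cell
#' type, or the held-out type lacking perturbed cells) are 0 with a warning.
#'
#' @param model an [invae_init()] model.
#' @param mat an [aem()] restricted to a binary condition pair.
#' @param sample use sampled latent codes instead of posterior means.
#' @return A list with scalars `ano_zc`, `ano_zs_control`, `ano_zp` and
#'   `groups`, the projection-group values (sets D1/D2 per cell type).
#' @export
navigation_losses <- function(model, mat, sample = FALSE) {
  stopifnot(inherits(model, "invae_model"), inherits(mat, "aem"))
  c_codes <- cell_type_codes(mat, model$cell_type_levels)
  s_codes <- condition_codes(mat)
  enc <- encode_fwd(NULL, model$params, mat$values, c_codes, s_codes,
                    model$config, model$mode, sample = sample)
  terms <- nav_terms_ag(NULL, model$params, enc, c_codes, s_codes,
                        model$config, model$mode, collect_groups = TRUE)
  val0 <- function(nd, what) {
    if (is.null(nd)) {
      warning("no usable groups for ", what, "; term is 0")
      0
    } else {
      as.numeric(ag_value(nd))
    }
  }
  list(
    ano_zc = if (model$mode == "full") val0(terms$ano_zc, "ano_zc") else 0,
    ano_zs_control = val0(terms$ano_zs_control, "ano_zs_control"),
    ano_zp = val0(terms$ano_zp, "ano_zp"),
    groups = terms$groups
  )
}

#' Compose the total training loss from its parts
#'
#' The base objective sums the non-target reconstruction, the weighted KL
#' decomposition (`mi + beta * tc + dwkl`) and the three navigation losses;
#' with `include_target_recon = TRUE` the target-cell reconstruction is added
#' as well (the variant applied every N-th update of the alternating
#' schedule).
#'
#' @param parts named list/vector with scalars `recon_other`, `recon_target`,
#'   `mi`, `tc`, `dwkl`, `ano_zc`, `ano_zs_control`, `ano_zp`. Reconstruction
#'   parts are mean squared errors; they enter the total multiplied by
#'   `config$recon_weight` (by default the gene count, i.e. Gaussian
#'   log-likelihood scale).
#' @param include_target_recon add the target reconstruction term.
#' @param config an [invae_config()] (supplies `beta` and `recon_weight`).
#' @return A `loss_breakdown` list: all parts plus `total` and the flag.
#' @export
total_loss <- function(parts, include_target_recon = FALSE, config) {
  need <- c("recon_other", "recon_target", "mi", "tc", "dwkl",
            "ano_zc", "ano_zs_control", "ano_zp")
  miss <- setdiff(need, names(parts))
  if (length(miss)) stop("missing loss parts: ", paste(miss, collapse = ", "))
  p <- lapply(parts[need], as.numeric)
  rw <- config$recon_weight
  total <- rw * p$recon_other + p$mi + config$beta * p$tc + p$dwkl +
    p$ano_zc + p$ano_zs_control + p$ano_zp +
    if (include_target_recon) rw * p$recon_target else 0
  structure(
    c(p, list(total = total, include_target_recon = include_target_recon)),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    paste0("<loss_breakdown> total %.4f (recon_other %.4f, recon_target %.4f,",
           " mi %.4f, tc %.4f, dwkl %.4f, ano_zc %.4f, ano_zs %.4f,",
           " ano_zp %.4f)%s\n"),
    x$total, x$recon_other, x$recon_target, x$mi, x$tc, x$dwkl,
    x$ano_zc, x$ano_zs_control, x$ano_zp,
    if (x$include_target_recon) " [target recon included]" else ""
  ))
  invisible(x)
}

#' @export
tidy.loss_breakdown <- function(x, ...) {
  tibble::tibble(
    term = c("recon_other", "recon_target", "mi", "tc", "dwkl",
             "ano_zc", "ano_zs_control", "ano_zp", "total"),
    value = c(x$recon_other, x$recon_target, x$mi, x$tc, x$dwkl,
              x$ano_zc, x$ano_zs_control, x$ano_zp, x$total)
  )
}
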