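# Alternating training loop: most updates minimize the base objective
# (reconstruction of non-target cells + KL decomposition + navigation
# losses); every N-th update additionally reconstructs the target cell
# type's control cells, so target information enters the homogeneous space
# without distorting the learned condition mapping.

adam_init <- function(params) {
  list(
    m = lapply(params, function(l) list(W = l$W * 0, b = l$b * 0)),
    v = lapply(params, function(l) list(W = l$W * 0, b = l$b * 0)),
    t = 0L
  )
}

# In-place fused update; `params` and the optimizer state are private deep
# copies owned by the training loop.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      if (is.null(g)) next
      adam_update_cpp(params[[nm]][[slot]], g, state$m[[nm]][[slot]],
                      state$v[[nm]][[slot]], lr, beta1, beta2, bc1, bc2, eps)
    }
  }
  state
}

deep_copy_params <- function(params) {
  lapply(params, function(l) list(W = l$W + 0, b = l$b + 0))
}

#' Trace of the alternating update schedule
#'
#' Reproduces the update-rule sequence of the training counter: starting from
#' `count = 0`, an update uses the base objective while `count < N` and the
#' target-including objective when `count == N` (which resets the counter);
#' the counter increments after every update. The first cycle therefore has
#' `N` base updates and steady-state cycles have `N - 1`.
#'
#' @param n_updates number of updates to trace.
#' @param N the alternation period.
#' @return Character vector of `"eq5"` (base) / `"eq6"` (target-including).
#' @export
alternation_schedule <- function(n_updates, N) {
  out <- character(n_updates)
  count <- 0L
  for (i in seq_len(n_updates)) {
    if (count < N) {
      out[i] <- "eq5"
    } else {
      out[i] <- "eq6"
      count <- 0L
    }
    count <- count + 1L
  }
  out
}

#' Train an INVAE model on a hold-out split
#'
#' Runs minibatch training with the alternating schedule. Every batch is
#' encoded with its true cell-type and condition codes, reconstructed through
#' both decoders, and scored with the full objective; gradients flow through
#' the reparameterized samples, the KL-decomposition estimator and the ANOVA
#' navigation losses, and a single Adam optimizer updates all components.
#' ANOVA terms whose grouping is not represented in a batch are skipped for
#' that batch.
#'
#' @param model an [invae_init()] model whose cell-type levels cover the data.
#' @param split a [hold_out_target()] split; training uses `split$train`.
#' @param config an [invae_config()]; defaults to the model's.
#' @param force_eq6 always include the target reconstruction (the
#'   "no alternating schedule" ablation).
#' @param verbose print a progress line every 25 epochs.
#' @return An object of class `invae_fit`: list with the trained `model` and
#'   `state` (final counter, per-epoch loss `history` tibble, per-update
#'   schedule `update_kinds`, and the seed).
#' @export
train_invae <- function(model, split, config = model$config,
                        force_eq6 = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "invae_model"), inherits(split, "holdout_split"))
  train <- split$train
  if (nrow(train$values) == 0L) stop("empty training set")
  x <- train$values
  c_codes <- cell_type_codes(train, model$cell_type_levels)
  s_codes <- condition_codes(train)
  is_target <- train$cell_types == split$target_cell_type
  n <- nrow(x)
  N <- config$n_alternation
  params <- deep_copy_params(model$params)
  opt <- adam_init(params)
  set.seed(config$seed)

  count <- 0L
  kinds <- character(0)
  part_names <- c("recon_other", "recon_target", "mi", "tc", "dwkl",
                  "ano_zc", "ano_zs_control", "ano_zp", "total")
  history <- matrix(NA_real_, config$epochs, length(part_names),
                    dimnames = list(NULL, part_names))

  warmup_epochs <- max(1, round(config$kl_warmup_frac * config$epochs))
  for (epoch in seq_len(config$epochs)) {
    kl_weight <- min(1, epoch / warmup_epochs)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    acc <- matrix(0, 0, length(part_names))
    for (st in starts) {
      idx <- perm[st:min(st + config$batch_size - 1L, n)]
      if (length(idx) < 2L) {
        warning("skipping batch of size ", length(idx))
        next
      }
      xb <- x[idx, , drop = FALSE]
      cb <- c_codes[idx]
      sb <- s_codes[idx]
      tb <- is_target[idx]

      tape <- ag_tape()
      leaves <- param_leaves(tape, params)
      enc <- encode_fwd(tape, leaves, xb, cb, sb, config, model$mode,
                        training = TRUE, sample = TRUE)
      zp <- project_fwd(tape, leaves, enc$z_s, sb, config, training = TRUE)
      xs <- decode_specific_fwd(tape, leaves, zp, config, training = TRUE)
      if (model$mode == "full") {
        xc <- decode_invariant_fwd(tape, leaves, enc$z_c, cb, config,
                                   training = TRUE)
        xhat <- ag_add(tape, xc, xs)
      } else {
        xhat <- xs
      }

      other_rows <- which(!tb)
      target_rows <- which(tb)
      recon_other <- if (length(other_rows)) {
        recon_loss_ag(tape, xhat, xb, other_rows)
      }
      recon_target <- if (length(target_rows)) {
        recon_loss_ag(tape, xhat, xb, target_rows)
      }
      kl <- kl_node_ag(tape, enc$z, enc$mu, enc$logvar, n, config$beta)
      nav <- nav_terms_ag(tape, leaves, enc, cb, sb, config, model$mode,
                          training = TRUE)

      use_eq6 <- force_eq6 || count >= N
      rw <- config$recon_weight
      nw <- config$nav_weight
      scale_or_null <- function(nd, w) {
        if (is.null(nd) || w == 1) nd else ag_scale(tape, nd, w)
      }
      terms <- list(
        if (!is.null(recon_other)) ag_scale(tape, recon_other, rw),
        ag_scale(tape, kl, kl_weight),
        scale_or_null(nav$ano_zc, nw),
        scale_or_null(nav$ano_zs_control, nw),
        scale_or_null(nav$ano_zp, nw)
      )
      if (use_eq6 && !is.null(recon_target)) {
        terms <- c(terms, list(ag_scale(tape, recon_target, rw)))
      }
      terms <- Filter(Negate(is.null), terms)
      total <- terms[[1L]]
      for (k in seq_along(terms)[-1L]) total <- ag_add(tape, total, terms[[k]])

      total_val <- as.numeric(ag_value(total))
      if (!is.finite(total_val)) {
        stop(sprintf(
          "non-finite loss at epoch %d (recon_other=%.3g, mi=%.3g, tc=%.3g, dwkl=%.3g)",
          epoch, if (is.null(recon_other)) 0 else ag_value(recon_other),
          kl$parts$mi, kl$parts$tc, kl$parts$dwkl
        ))
      }
      ag_backward(tape, total)
      grads <- lapply(leaves, function(l) list(W = l$W$grad, b = l$b$grad))
      if (is.finite(config$grad_clip)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) {
          (if (is.null(g$W)) 0 else sum(g$W * g$W)) +
            (if (is.null(g$b)) 0 else sum(g$b * g$b))
        }, 1.0)))
        if (gnorm > config$grad_clip) {
          sc <- config$grad_clip / gnorm
          grads <- lapply(grads, function(g) {
            list(W = if (is.null(g$W)) NULL else g$W * sc,
                 b = if (is.null(g$b)) NULL else g$b * sc)
          })
        }
      }
      opt <- adam_step(params, grads, opt, config$learning_rate)

      if (!force_eq6) {
        if (count >= N) count <- 0L
        count <- count + 1L
      }
      kinds <- c(kinds, if (use_eq6) "eq6" else "eq5")

      val_or0 <- function(nd) if (is.null(nd)) 0 else as.numeric(ag_value(nd))
      acc <- rbind(acc, c(
        val_or0(recon_other), val_or0(recon_target), kl$parts$mi,
        kl$parts$tc, kl$parts$dwkl, val_or0(nav$ano_zc),
        val_or0(nav$ano_zs_control), val_or0(nav$ano_zp), total_val
      ))
    }
    history[epoch, ] <- colMeans(acc)
    if (verbose && epoch %% 25L == 0L) {
      message(sprintf("epoch %d/%d total %.4f", epoch, config$epochs,
                      history[epoch, "total"]))
    }
  }

  model$params <- params
  state <- structure(
    list(
      counter = count,
      epochs = config$epochs,
      history = tibble::as_tibble(cbind(
        data.frame(epoch = seq_len(config$epochs)), as.data.frame(history)
      )),
      update_kinds = kinds,
      seed = config$seed
    ),
    class = "training_state"
  )
  structure(list(model = model, state = state), class = "invae_fit")
}

#' Train with an ablation mode
#'
#' @param model an [invae_init()] model.
#' @param split a [hold_out_target()] split.
#' @param config an [invae_config()].
#' @param mode one of `"full"` (identical to [train_invae()]),
#'   `"no_alternation"` (the target reconstruction is included in every
#'   update) and `"no_decoder1"` (decoder 1 removed; all latent dimensions are
#'   condition-specific, routed through the projection layer, and the
#'   condition-invariance navigation loss is dropped).
#' @return An `invae_fit`.
#' @export
train_ablation <- function(model, split, config = model$config,
                           mode = c("full", "no_alternation", "no_decoder1")) {
  mode <- match.arg(mode)
  switch(mode,
    full = train_invae(model, split, config),
    no_alternation = train_invae(model, split, config, force_eq6 = TRUE),
    no_decoder1 = {
      if (model$mode != "no_decoder1") {
        model <- invae_init(config, model$cell_type_levels,
                            mode = "no_decoder1")
      }
      train_invae(model, split, config)
    }
  )
}

#' @export
print.invae_fit <- function(x, ...) {
  h <- x$state$history
  cat(sprintf(
    "<invae_fit> %s | %d epochs | total loss %.4f -> %.4f\n",
    x$model$mode, x$state$epochs, h$total[1L], h$total[nrow(h)]
  ))
  invisible(x)
}

#' Per-epoch loss history in long form
#'
#' @param x an `invae_fit`.
#' @param ... unused.
#' @return A tibble with columns `epoch`, `term`, `value`.
#' @export
tidy.invae_fit <- function(x, ...) {
  h <- x$state$history
  terms <- setdiff(names(h), "epoch")
  tibble::tibble(
    epoch = rep(h$epoch, times = length(terms)),
    term = rep(terms, each = nrow(h)),
    value = unlist(h[terms], use.names = FALSE)
  )
}

#' One-row training summary
#'
#' @param x an `invae_fit`.
#' @param ... unused.
#' @return A one-row tibble with the mode, epoch count and first/last totals.
#' @export
glance.invae_fit <- function(x, ...) {
  h <- x$state$history
  tibble::tibble(
    mode = x$model$mode, epochs = x$state$epochs,
    n_updates = length(x$state$update_kinds),
    total_first = h$total[1L], total_last = h$total[nrow(h)],
    recon_other_last = h$recon_other[nrow(h)]
  )
}

#' Plot the training loss history
#'
#' @param object an `invae_fit`.
#' @param terms which loss terms to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.invae_fit <- function(object, terms = c("total", "recon_other",
                                                 "ano_zc", "tc"), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()")
  }
  df <- tidy.invae_fit(object)
  df <- df[df$term %in% terms, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = "term") +
    ggplot2::theme_minimal()
}
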