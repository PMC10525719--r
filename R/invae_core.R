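#' Model and training hyperparameters
#'
#' Architecture and optimization settings of the information-navigated VAE.
#' Defaults follow the published configuration: a 3-layer encoder (800, 800,
#' 128 units) emitting a 30-dim condition-invariant and a 30-dim
#' condition-specific latent part, a single 128-unit projection layer, two
#' decoders (128/800/800 and 800/800 hidden units, linear outputs), dropout
#' 0.2, Adam at learning rate 0.001, total-correlation weight `beta = 2`, and
#' an alternation period `n_alternation = 5` for the training schedule.
#'
#' @param input_dim number of genes.
#' @param encoder_hidden,decoder1_hidden,decoder2_hidden hidden layer widths.
#' @param latent_c_dim,latent_s_dim sizes of the condition-invariant and
#'   condition-specific latent parts.
#' @param projection_dim width of the projection layer.
#' @param dropout_rate dropout probability on hidden layers during training.
#' @param beta weight on the total-correlation term.
#' @param learning_rate Adam step size.
#' @param n_alternation period N of the alternating update schedule.
#' @param epochs training epochs.
#' @param batch_size minibatch size. The default 128 keeps several cells per
#'   (cell type, condition) ANOVA group at typical study sizes while giving
#'   Adam multiple updates per epoch.
#' @param seed RNG seed controlling initialization, shuffling, dropout and
#'   reparameterization noise.
#' @param anova_epsilon additive stabilizer on the ANOVA within-group mean
#'   square during training.
#' @param kl_warmup_frac fraction of epochs over which the KL-decomposition
#'   weight is linearly annealed from 0 to 1. Warm-up keeps the encoder from
#'   collapsing to an uninformative posterior before the decoders learn to
#'   use the latent codes.
#' @param grad_clip global gradient-norm clip applied before each update;
#'   `Inf` disables. The ANOVA terms make early gradients heavy-tailed.
#' @param recon_weight weight of the reconstruction terms in the total loss.
#'   The default (`NULL`) uses `10 * input_dim`: a Gaussian reconstruction
#'   likelihood with per-gene variance 0.1 (a typical residual-noise scale
#'   for log-normalized expression) summed over genes. With a much smaller
#'   weight the KL terms dominate and the posterior collapses to an
#'   uninformative constant, which ruins mean-based prediction.
#' @param nav_weight common weight on the three ANOVA navigation losses
#'   (default 1, the plain sum).
#' @return An `invae_config` list.
#' @export
invae_config <- function(input_dim,
                         encoder_hidden = c(800, 800, 128),
                         latent_c_dim = 30, latent_s_dim = 30,
                         projection_dim = 128,
                         decoder1_hidden = c(128, 800, 800),
                         decoder2_hidden = c(800, 800),
                         dropout_rate = 0.2, beta = 2,
                         learning_rate = 0.001, n_alternation = 5,
                         epochs = 500, batch_size = 128, seed = 1,
                         anova_epsilon = 1e-8, kl_warmup_frac = 0.25,
                         grad_clip = 1000, recon_weight = NULL,
                         nav_weight = 1) {
  if (is.null(recon_weight)) recon_weight <- 10 * as.numeric(input_dim)
  stopifnot(
    input_dim >= 1, all(encoder_hidden >= 1), latent_c_dim >= 1,
    latent_s_dim >= 1, projection_dim >= 1, all(decoder1_hidden >= 1),
    all(decoder2_hidden >= 1), dropout_rate >= 0, dropout_rate < 1,
    beta >= 0, learning_rate > 0, n_alternation >= 1, epochs >= 1,
    batch_size >= 2, anova_epsilon >= 0, recon_weight > 0,
    kl_warmup_frac >= 0, kl_warmup_frac <= 1, grad_clip > 0, nav_weight >= 0
  )
  structure(
    list(
      input_dim = as.integer(input_dim),
      encoder_hidden = as.integer(encoder_hidden),
      latent_c_dim = as.integer(latent_c_dim),
      latent_s_dim = as.integer(latent_s_dim),
      projection_dim = as.integer(projection_dim),
      decoder1_hidden = as.integer(decoder1_hidden),
      decoder2_hidden = as.integer(decoder2_hidden),
      dropout_rate = dropout_rate, beta = beta,
      learning_rate = learning_rate,
      n_alternation = as.integer(n_alternation),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      seed = as.integer(seed), anova_epsilon = anova_epsilon,
      kl_warmup_frac = kl_warmup_frac, grad_clip = grad_clip,
      recon_weight = recon_weight, nav_weight = nav_weight
    ),
    class = "invae_config"
  )
}

init_dense <- function(n_in, n_out, gain = sqrt(2)) {
  list(
    W = matrix(stats::rnorm(n_in * n_out, 0, gain / sqrt(n_in)), n_in, n_out),
    b = matrix(0, 1L, n_out)
  )
}

#' Initialize an INVAE model
#'
#' Builds the encoder, projection layer and decoder weights (He-normal hidden
#' layers, small-variance linear heads; the log-variance head starts near a
#' unit-variance posterior).
#'
#' @param config an [invae_config()].
#' @param cell_type_levels character vector of all cell-type labels the model
#'   will see; their sorted order defines the integer cell-type codes.
#' @param mode `"full"` or `"no_decoder1"`. In the ablated mode decoder 1 is
#'   absent and all latent dimensions are treated as condition-specific and
#'   routed through the projection layer.
#' @return An object of class `invae_model`.
#' @export
invae_init <- function(config, cell_type_levels, mode = c("full", "no_decoder1")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "invae_config"))
  set.seed(config$seed)
  G <- config$input_dim
  lc <- config$latent_c_dim
  ls <- config$latent_s_dim
  dz <- lc + ls
  eh <- config$encoder_hidden
  p <- list()
  p$enc1 <- init_dense(G + 2L, eh[1])
  p$enc2 <- init_dense(eh[1], eh[2])
  p$enc3 <- init_dense(eh[2], eh[3])
  p$mu_head <- init_dense(eh[3], dz, gain = 1)
  p$lv_head <- init_dense(eh[3], dz, gain = 0.01)
  if (mode == "full") {
    d1 <- config$decoder1_hidden
    p$d1_1 <- init_dense(lc + 1L, d1[1])
    p$d1_2 <- init_dense(d1[1], d1[2])
    p$d1_3 <- init_dense(d1[2], d1[3])
    p$d1_out <- init_dense(d1[3], G, gain = 1)
  }
  proj_in <- if (mode == "full") ls else dz
  p$proj <- init_dense(proj_in + 1L, config$projection_dim)
  d2 <- config$decoder2_hidden
  p$d2_1 <- init_dense(config$projection_dim, d2[1])
  p$d2_2 <- init_dense(d2[1], d2[2])
  p$d2_out <- init_dense(d2[2], G, gain = 1)
  structure(
    list(
      config = config, params = p, mode = mode,
      cell_type_levels = sort(unique(as.character(cell_type_levels)))
    ),
    class = "invae_model"
  )
}

#' @export
print.invae_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(l) length(l$W) + length(l$b), 1))
  cat(sprintf(
    "<invae_model> %s | %d genes -> %d+%d latent | %s parameters | %d cell types\n",
    x$mode, x$config$input_dim, x$config$latent_c_dim, x$config$latent_s_dim,
    format(n_par, big.mark = ","), length(x$cell_type_levels)
  ))
  invisible(x)
}

# wrap every weight matrix as an autodiff leaf
param_leaves <- function(tape, params) {
  lapply(params, function(l) list(W = ag_leaf(tape, l$W), b = ag_leaf(tape, l$b)))
}

dense_fwd <- function(tape, x, layer, activation = "relu", dropout = 0,
                      training = FALSE) {
  h <- ag_add(tape, ag_matmul(tape, x, layer$W), layer$b)
  if (activation == "relu") h <- ag_relu(tape, h)
  if (training && dropout > 0) {
    dims <- dim(ag_value(h))
    mask <- matrix(
      (stats::runif(prod(dims)) >= dropout) / (1 - dropout), dims[1], dims[2]
    )
    h <- ag_mul(tape, h, mask)
  }
  h
}

# Forward passes. `P` holds either raw parameter matrices (evaluation) or
# autodiff leaves (training); data and annotation codes are constants.

encode_fwd <- function(tape, P, x, c_codes, s_codes, config, mode,
                       training = FALSE, sample = FALSE) {
  M <- nrow(x)
  input <- cbind(x, as.numeric(c_codes), as.numeric(s_codes))
  dr <- config$dropout_rate
  h <- dense_fwd(tape, input, P$enc1, "relu", dr, training)
  h <- dense_fwd(tape, h, P$enc2, "relu", dr, training)
  h <- dense_fwd(tape, h, P$enc3, "relu", dr, training)
  mu <- ag_add(tape, ag_matmul(tape, h, P$mu_head$W), P$mu_head$b)
  lv <- ag_add(tape, ag_matmul(tape, h, P$lv_head$W), P$lv_head$b)
  if (sample) {
    dz <- ncol(ag_value(mu))
    eps <- matrix(stats::rnorm(M * dz), M, dz)
    sd_half <- ag_exp(tape, ag_scale(tape, lv, 0.5))
    z <- ag_add(tape, mu, ag_mul(tape, sd_half, eps))
  } else {
    z <- mu
  }
  lc <- config$latent_c_dim
  dz <- config$latent_c_dim + config$latent_s_dim
  if (mode == "full") {
    list(
      mu = mu, logvar = lv, z = z,
      z_c = ag_cols(tape, z, seq_len(lc)),
      z_s = ag_cols(tape, z, (lc + 1L):dz)
    )
  } else {
    list(mu = mu, logvar = lv, z = z, z_c = NULL, z_s = z)
  }
}

decode_invariant_fwd <- function(tape, P, z_c, c_codes, config,
                                 training = FALSE) {
  dr <- config$dropout_rate
  input <- ag_cbind(tape, z_c, matrix(as.numeric(c_codes), ncol = 1L))
  h <- dense_fwd(tape, input, P$d1_1, "relu", dr, training)
  h <- dense_fwd(tape, h, P$d1_2, "relu", dr, training)
  h <- dense_fwd(tape, h, P$d1_3, "relu", dr, training)
  dense_fwd(tape, h, P$d1_out, "linear")
}

project_fwd <- function(tape, P, z_s, s_codes, config, training = FALSE) {
  M <- nrow(ag_value(z_s))
  s_col <- matrix(rep_len(as.numeric(s_codes), M), ncol = 1L)
  input <- ag_cbind(tape, z_s, s_col)
  dense_fwd(tape, input, P$proj, "relu", config$dropout_rate, training)
}

decode_specific_fwd <- function(tape, P, z_p, config, training = FALSE) {
  dr <- config$dropout_rate
  h <- dense_fwd(tape, z_p, P$d2_1, "relu", dr, training)
  h <- dense_fwd(tape, h, P$d2_2, "relu", dr, training)
  dense_fwd(tape, h, P$d2_out, "linear")
}

resolve_codes <- function(model, x, c_codes, s_codes) {
  if (inherits(x, "aem")) {
    mat <- x
    x <- mat$values
    if (is.null(c_codes)) c_codes <- cell_type_codes(mat, model$cell_type_levels)
    if (is.null(s_codes)) s_codes <- condition_codes(mat)
  }
  x <- as.matrix(x)
  if (ncol(x) != model$config$input_dim) {
    stop("input has ", ncol(x), " genes; model expects ", model$config$input_dim)
  }
  if (!all(s_codes %in% c(0, 1))) stop("condition codes must be 0 or 1")
  list(x = x, c = rep_len(as.numeric(c_codes), nrow(x)),
       s = rep_len(as.numeric(s_codes), nrow(x)))
}

#' Encode cells into the two latent parts
#'
#' Runs the encoder in evaluation mode (no dropout). With `sample = FALSE`
#' the latent samples equal the posterior means.
#'
#' @param model a trained or freshly initialized [invae_init()] model.
#' @param x an [aem()] object (annotations taken from it) or a numeric matrix.
#' @param c_codes,s_codes integer cell-type / condition codes, recycled to the
#'   number of cells; derived from `x` when it is an [aem()].
#' @param sample draw latent samples via the reparameterization transform
#'   instead of returning the posterior mean.
#' @return A list with matrices `mu_c`, `logvar_c`, `mu_s`, `logvar_s`,
#'   `z_c`, `z_s` and the concatenated `mu`, `logvar`, `z`. In
#'   `"no_decoder1"` mode `z_c` is `NULL` and `z_s` spans all dimensions.
#' @export
encode <- function(model, x, c_codes = NULL, s_codes = NULL, sample = FALSE) {
  stopifnot(inherits(model, "invae_model"))
  inp <- resolve_codes(model, x, c_codes, s_codes)
  enc <- encode_fwd(NULL, model$params, inp$x, inp$c, inp$s, model$config,
                    model$mode, training = FALSE, sample = sample)
  lc <- model$config$latent_c_dim
  dz <- lc + model$config$latent_s_dim
  mu <- ag_value(enc$mu); lv <- ag_value(enc$logvar); z <- ag_value(enc$z)
  list(
    mu = mu, logvar = lv, z = z,
    mu_c = if (model$mode == "full") mu[, seq_len(lc), drop = FALSE],
    logvar_c = if (model$mode == "full") lv[, seq_len(lc), drop = FALSE],
    mu_s = if (model$mode == "full") mu[, (lc + 1L):dz, drop = FALSE] else mu,
    logvar_s = if (model$mode == "full") lv[, (lc + 1L):dz, drop = FALSE] else lv,
    z_c = if (model$mode == "full") z[, seq_len(lc), drop = FALSE],
    z_s = if (model$mode == "full") z[, (lc + 1L):dz, drop = FALSE] else z
  )
}

#' Decode the condition-invariant latent part
#'
#' @param model an [invae_init()] model in `"full"` mode.
#' @param z_c matrix of condition-invariant codes (cells x latent_c_dim).
#' @param c_codes integer cell-type codes, recycled.
#' @return A cells x genes matrix.
#' @export
decode_invariant <- function(model, z_c, c_codes) {
  stopifnot(inherits(model, "invae_model"))
  if (model$mode != "full") stop("model has no decoder 1 (mode '", model$mode, "')")
  z_c <- as.matrix(z_c)
  ag_value(decode_invariant_fwd(NULL, model$params, z_c,
                                rep_len(as.numeric(c_codes), nrow(z_c)),
                                model$config))
}

#' Project condition-specific codes under an inserted condition
#'
#' Concatenates the condition code to the condition-specific latent part and
#' applies the (ReLU) projection layer; the inserted code chooses which
#' conditional space the codes are mapped into.
#'
#' @param model an [invae_init()] model.
#' @param z_s matrix of condition-specific codes.
#' @param s_insert condition code 0 (control) or 1 (perturbed), recycled.
#' @return A cells x projection_dim matrix.
#' @export
project_latent <- function(model, z_s, s_insert) {
  stopifnot(inherits(model, "invae_model"))
  if (!all(s_insert %in% c(0, 1))) stop("s_insert must be 0 or 1")
  ag_value(project_fwd(NULL, model$params, as.matrix(z_s), s_insert,
                       model$config))
}

#' Decode projected condition-specific codes
#'
#' @param model an [invae_init()] model.
#' @param z_p matrix of projection-layer outputs (cells x projection_dim).
#' @return A cells x genes matrix.
#' @export
decode_specific <- function(model, z_p) {
  stopifnot(inherits(model, "invae_model"))
  ag_value(decode_specific_fwd(NULL, model$params, as.matrix(z_p),
                               model$config))
}

#' Reconstruct cells through both decoders
#'
#' The reconstruction is the sum of the condition-invariant decoding and the
#' decoded projection of the condition-specific part (only the latter in
#' `"no_decoder1"` mode).
#'
#' @inheritParams encode
#' @return A list with `x_hat`, the per-decoder parts `x_c` and `x_s`, the
#'   latent code list (as in [encode()]) and the projection `z_p`.
#' @export
reconstruct <- function(model, x, c_codes = NULL, s_codes = NULL,
                        sample = FALSE) {
  stopifnot(inherits(model, "invae_model"))
  inp <- resolve_codes(model, x, c_codes, s_codes)
  latent <- encode(model, inp$x, inp$c, inp$s, sample = sample)
  z_p <- project_latent(model, latent$z_s, inp$s)
  x_s <- decode_specific(model, z_p)
  if (model$mode == "full") {
    x_c <- decode_invariant(model, latent$z_c, inp$c)
    x_hat <- x_c + x_s
  } else {
    x_c <- matrix(0, nrow(x_s), ncol(x_s))
    x_hat <- x_s
  }
  dimnames(x_hat) <- dimnames(inp$x)
  list(x_hat = x_hat, x_c = x_c, x_s = x_s, latent = latent, z_p = z_p)
}

#' Save / load model checkpoints
#'
#' The checkpoint embeds the full configuration and a hash of it; loading
#' verifies the hash so silently mismatched configurations are caught.
#'
#' @param model an [invae_init()] model.
#' @param path checkpoint file.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "invae_model"))
  payload <- list(
    config = model$config, params = model$params, mode = model$mode,
    cell_type_levels = model$cell_type_levels,
    config_hash = rlang::hash(model$config)
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(rlang::hash(payload$config), payload$config_hash)) {
    stop("checkpoint config hash mismatch; file is corrupt or tampered")
  }
  structure(
    list(
      config = payload$config, params = payload$params, mode = payload$mode,
      cell_type_levels = payload$cell_type_levels
    ),
    class = "invae_model"
  )
}
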