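# Shared fixtures: a small architecture for fast unit tests, a deterministic
# toy dataset, and memoized full-architecture training runs reused across the
# acceptance tests.

tiny_config <- function(n_genes = 12, ...) {
  args <- utils::modifyList(
    list(
      input_dim = n_genes,
      encoder_hidden = c(24, 24, 12),
      latent_c_dim = 4, latent_s_dim = 4,
      projection_dim = 12,
      decoder1_hidden = c(8, 16, 16),
      decoder2_hidden = c(16, 16),
      epochs = 3, batch_size = 32, seed = 1
    ),
    list(...)
  )
  do.call(invae_config, args)
}

# small annotated matrix: K cell types x 2 conditions x n cells, binary-coded
tiny_dataset <- function(K = 3, n = 8, G = 12, seed = 42, noise_sd = 0.2) {
  cfg <- synthetic_config(
    n_cell_types = K, n_genes = G, cells_per_group = n,
    shared_response = c(rep(1, 3), numeric(G - 3)),
    noise_sd = noise_sd, seed = seed
  )
  gen <- generate_synthetic(cfg)
  restrict_to_pair(gen$data, "control", "perturbed")
}

tiny_split <- function(...) {
  suppressMessages(hold_out_target(tiny_dataset(...), "type_1"))
}

# Scenario pipeline at full architecture; memoized because several acceptance
# properties are checked on the same trained models.
.run_cache <- new.env(parent = emptyenv())

scenario_split <- function(scenario, seed, cells_per_group = 50) {
  gen <- generate_synthetic(make_benchmark_scenario(
    scenario, seed = seed, cells_per_group = cells_per_group
  ))
  mat <- restrict_to_pair(gen$data, "control", "perturbed")
  list(gen = gen, mat = mat,
       split = suppressMessages(hold_out_target(mat, "type_1")))
}

scenario_run <- function(scenario, seed, epochs, mode = "full",
                         cells_per_group = 50) {
  key <- paste(scenario, seed, epochs, mode, cells_per_group, sep = "|")
  if (!is.null(.run_cache[[key]])) {
    return(.run_cache[[key]])
  }
  sc <- scenario_split(scenario, seed, cells_per_group)
  mc <- invae_config(input_dim = ncol(sc$mat$values), epochs = epochs,
                     seed = seed)
  model0 <- invae_init(mc, unique(sc$mat$cell_types))
  fit <- train_ablation(model0, sc$split, mode = mode)
  res <- list(
    gen = sc$gen, mat = sc$mat, split = sc$split, model0 = model0, fit = fit,
    report = evaluate_holdout(fit$model, sc$split),
    baseline = evaluate_prediction(sc$split$target_control$values, sc$split)
  )
  .run_cache[[key]] <- res
  res
}
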