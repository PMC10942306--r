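# Shared fixtures, built once per test run and memoised. The micro scale is
# for unit tests (seconds); the tiny scale matches the package's default
# study conditions and is used by the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

micro_spec <- function(seed = 7L) {
  simulation_spec(n_cell_types = 2L, cells_per_type_per_time = 20L,
                  atac_cells_per_type_per_time = 12L,
                  genes = 60L, peaks = 40L,
                  n_sex_genes = 8L, n_escape_genes = 4L,
                  n_lag_pairs = 10L, seed = seed)
}

micro_sim <- function() memo("micro_sim", function() {
  simulate_multiomic_timeseries(micro_spec())
})

micro_config <- function(seed = 1L, max_epochs = 12L, ...) {
  model_config(latent_dim = 8L, hidden_width = 48L, time_proj_width = 16L,
               time_cfg = time_encoding_config(d = 20L),
               max_epochs = max_epochs, patience = 4L, batch_size = 128L,
               dis_width = 24L, seed = seed, ...)
}

micro_rna_model <- function() memo("micro_rna_model", function() {
  sim <- micro_sim()
  splits <- make_splits(sim$data, split_spec(seed = 1))
  train_single_modality(sim$data, splits, micro_config(seed = 1))
})

micro_mm_model <- function() memo("micro_mm_model", function() {
  sim <- micro_sim()
  splits <- make_splits(sim$data, split_spec(seed = 1))
  train_multimodal(sim$data, splits, micro_config(seed = 1), lambda_mse = 100)
})

tiny_sim <- function(seed = 1L) {
  key <- paste0("tiny_sim_", seed)
  memo(key, function() simulate_multiomic_timeseries(default_acceptance_spec("tiny", seed = seed)))
}

# study-scale configuration used by the acceptance experiments; problem
# sizes are documented in the methods vignette
tiny_config <- function(seed, ...) {
  model_config(latent_dim = 16L, hidden_width = 128L,
               max_epochs = 100L, patience = 12L, batch_size = 256L,
               seed = seed, ...)
}
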