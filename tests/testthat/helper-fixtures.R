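# Shared test fixtures. Parsed molecular graphs are cached per session so
# each molecule goes through the OpenBabel round-trip once.

.fixture_cache <- new.env(parent = emptyenv())

fx_graph <- function(smiles) {
  key <- smiles
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- parse_smiles(smiles)
  .fixture_cache[[key]]
}

# simulated table with the frozen U251 coefficients planted as truth
sim_model3_table <- function(n = 150, noise_sd = 0.1, k_noise = 7, seed) {
  m3 <- published_model("model3")
  cfg <- sim_config(n, default_sim_descriptors(k_noise),
                    true_beta = m3$coefficients, intercept = m3$intercept,
                    noise_sd = noise_sd, seed = seed)
  simulate_descriptor_table(cfg)
}

# random continuous descriptor/activity table for regression checks
random_table <- function(n, k, seed, beta = NULL, noise_sd = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("d", seq_len(k))))
  if (is.null(beta)) beta <- rnorm(k)
  y <- as.vector(X %*% beta) + rnorm(n, 0, noise_sd)
  df <- data.frame(compound_id = paste0("c", seq_len(n)), log_ic50 = y,
                   stringsAsFactors = FALSE)
  activity_table(cbind(df, as.data.frame(X)))
}
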