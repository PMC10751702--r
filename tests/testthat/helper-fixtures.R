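# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# the desk-scale study scene: one straight 200-bp target
desk_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- build_bdna(200, seed = 1)
  .fixtures$model
}

desk_ctx <- function() {
  if (is.null(.fixtures$ctx))
    .fixtures$ctx <- tracking_context(desk_model())
  .fixtures$ctx
}

# fixture-library variant with a single non-zero channel (elastic), used for
# attenuation and mean-free-path closed-form checks
elastic_only_params <- function(A_elastic = 2e-2) {
  p <- xsec_fixture_params()
  for (k in names(p$dea)) p$dea[[k]]$res <-
    lapply(p$dea[[k]]$res, function(r) { r[["A"]] <- 0; r })
  p$excitation$A <- 0
  p$ionization$A <- 0
  p$elastic$A <- A_elastic
  p
}

# library with every amplitude zeroed except DEA (for break-channel checks)
dea_only_params <- function() {
  p <- xsec_fixture_params()
  p$excitation$A <- 0
  p$ionization$A <- 0
  p$elastic$A <- 0
  p
}

# random break tables for clustering property tests
random_breaks <- function(n, bp_range = 60L) {
  data.table::data.table(
    target = 1L,
    strand = sample(1:2, n, replace = TRUE),
    bp_index = sample.int(bp_range, n, replace = FALSE),
    cause = "dea",
    history_id = seq_len(n))
}

# energy sweep at the desk scale, shared between acceptance blocks
desk_sweep <- function(n_histories = 1e5,
                       energies = c(4, 6, 10, 15, 20, 30, 50, 100, 200,
                                    500)) {
  key <- paste0("sweep_", n_histories)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  model <- desk_model()
  ctx <- desk_ctx()
  rules <- damage_rules()
  rows <- lapply(energies, function(e) {
    src <- source_for_model(model, e, n_histories = n_histories)
    sim <- run_simulation(ctx, src, seed = 20260925)
    s <- summarize_run(sim, model, rules)
    scored <- score_breaks(sim$events, model, rules)
    s$break_causes <- list(scored$breaks$cause)
    s
  })
  .fixtures[[key]] <- data.table::rbindlist(rows)
  .fixtures[[key]]
}
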