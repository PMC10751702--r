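# Aggregation of events and breaks into doses, yields and spectra.

#' Absorbed dose in Gray
#'
#' `dose = E_deposited[J] / mass[kg]` with the pinned conversion constants
#' 1 eV = 1.602176634e-19 J and 1 Da = 1.66053907e-27 kg.
#'
#' @param E_deposited_ev deposited energy, eV.
#' @param mass_da absorbing mass, Daltons (> 0).
#' @return Dose in Gy.
#' @export
dose_gray <- function(E_deposited_ev, mass_da) {
  if (any(mass_da <= 0)) stop("mass must be > 0")
  (E_deposited_ev * EV_TO_JOULE) / (mass_da * DALTON_TO_KG)
}

#' Strand-break yields
#'
#' Per-incident-electron yields (`count / n_histories`) and
#' per-Gray-per-Dalton yields (`Y = count / (dose * mass)`).
#'
#' @param n_ssb,n_dsb break counts.
#' @param n_histories number of incident electrons (>= 1).
#' @param dose dose in Gy; must be > 0 when any breaks were counted.
#' @param mass_da DNA mass, Daltons.
#' @return Named list: `ssb_per_electron`, `dsb_per_electron`, `Y_ssb`,
#'   `Y_dsb` (Gy^-1 Da^-1).
#' @export
break_yields <- function(n_ssb, n_dsb, n_histories, dose, mass_da) {
  stopifnot(n_histories >= 1)
  if (dose == 0 && (n_ssb > 0 || n_dsb > 0))
    stop("zero dose with non-zero breaks is inconsistent")
  list(ssb_per_electron = n_ssb / n_histories,
       dsb_per_electron = n_dsb / n_histories,
       Y_ssb = if (dose > 0) n_ssb / (dose * mass_da) else 0,
       Y_dsb = if (dose > 0) n_dsb / (dose * mass_da) else 0)
}

#' Interaction-count spectrum
#'
#' Exact per-channel tallies of an event stream; vibrational and electronic
#' excitation are reported both separately and merged under `excitation`.
#'
#' @param events event table.
#' @return Named integer vector over the event channels plus `excitation`.
#' @export
interaction_spectrum <- function(events) {
  ev <- as.data.table(events)
  counts <- setNames(integer(length(EVENT_CHANNELS)), EVENT_CHANNELS)
  if (nrow(ev)) {
    tab <- ev[, .N, by = channel]
    counts[tab$channel] <- tab$N
  }
  c(counts,
    excitation = unname(counts["vibrational_excitation"] +
                          counts["electronic_excitation"]))
}

#' Percentage of broken nucleotides
#'
#' 100 x (distinct broken nucleotide positions) / (2 x n_bp x n_targets),
#' the number of single breaks divided by the total number of strands.
#'
#' @param breaks break table from [score_breaks()].
#' @param n_bp base pairs per target.
#' @param n_targets number of targets.
#' @return Percentage in [0, 100].
#' @export
ssb_percentage <- function(breaks, n_bp, n_targets = 1L) {
  stopifnot(n_bp >= 1)
  br <- as.data.table(breaks)
  if (!nrow(br)) return(0)
  distinct <- nrow(unique(br[, c("target", "strand", "bp_index")]))
  100 * distinct / (2 * n_bp * n_targets)
}

#' Summarize one simulation into the standard per-energy statistics
#'
#' Runs break scoring and DSB clustering on the event stream and assembles
#' the per-energy summary row: channel counts, deposited energy (interaction
#' deposits plus cutoff kills, which happen at the last interaction site
#' inside the DNA), dose, break counts, per-electron and per-Gy-per-Da
#' yields, broken-nucleotide percentage and the fraction of DSBs whose two
#' breaks come from different primary histories.
#'
#' @param sim a `simulation_result`.
#' @param model the irradiated `dna_model`.
#' @param rules a `damage_rules` object.
#' @return One-row `data.table`.
#' @export
summarize_run <- function(sim, model, rules = damage_rules()) {
  spec <- interaction_spectrum(sim$events)
  scored <- score_breaks(sim$events, model, rules)
  dsb <- cluster_dsb(scored$breaks, rules)
  n_ssb <- nrow(scored$breaks)
  n_dsb <- nrow(dsb)
  if (!rules$count_dsb_constituents_in_ssb) n_ssb <- n_ssb - 2L * n_dsb
  E_dep <- sum(sim$ledger$E_deposited) + sum(sim$ledger$E_cutoff)
  dose <- dose_gray(E_dep, model$mass)
  y <- break_yields(n_ssb, n_dsb, sim$n_histories, dose, model$mass)
  data.table(
    energy_ev = sim$energy, n_histories = sim$n_histories, seed = sim$seed,
    n_elastic = spec[["elastic"]],
    n_vibrational = spec[["vibrational_excitation"]],
    n_electronic = spec[["electronic_excitation"]],
    n_excitation = spec[["excitation"]],
    n_ionization = spec[["ionization"]],
    n_dea = spec[["dea"]],
    E_deposited_ev = E_dep,
    dose_gy = dose,
    dose_gy_per_electron = dose / sim$n_histories,
    n_ssb = n_ssb, n_dsb = n_dsb,
    n_base_damage = nrow(scored$base_damage),
    ssb_per_electron = y$ssb_per_electron,
    dsb_per_electron = y$dsb_per_electron,
    Y_ssb = y$Y_ssb, Y_dsb = y$Y_dsb,
    ssb_percentage = ssb_percentage(scored$breaks, model$n_bp,
                                    model$n_targets),
    cross_history_dsb_fraction =
      if (n_dsb > 0) mean(dsb$cross_history) else 0)
}

#' Repeat a simulation and aggregate mean and standard deviation
#'
#' Runs `n_repeats` independent simulations with distinct seeds derived from
#' the master seed by a counter scheme, summarizes each, and reports the
#' sample mean and sample standard deviation (n-1 denominator) of every
#' numeric summary quantity.  With a single repeat the standard deviation is
#' reported as 0 with a warning.
#'
#' @param ctx a `tracking_context`.
#' @param energy beam energy, eV.
#' @param n_histories histories per repeat.
#' @param n_repeats number of repeats (>= 1).
#' @param master_seed integer master seed.
#' @param rules a `damage_rules` object.
#' @param source_distance stand-off of the source, nm.
#' @return List with `per_repeat` (one summary row per repeat) and `summary`
#'   (long table: quantity, mean, sd).
#' @export
repeat_and_aggregate <- function(ctx, energy, n_histories, n_repeats = 3L,
                                 master_seed = 1L, rules = damage_rules(),
                                 source_distance = 40) {
  stopifnot(n_repeats >= 1)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    src <- source_for_model(ctx$model, energy, distance = source_distance,
                            n_histories = n_histories)
    sim <- run_simulation(ctx, src, seed = derive_seed(master_seed, r * 1e6))
    rows[[r]] <- summarize_run(sim, ctx$model, rules)
  }
  per_repeat <- rbindlist(rows)
  num_cols <- setdiff(names(per_repeat), c("seed"))
  if (n_repeats == 1L)
    warning("single repeat: standard deviations reported as 0")
  agg <- data.table(
    quantity = num_cols,
    mean = vapply(num_cols, function(cn) mean(per_repeat[[cn]]), 0),
    sd = vapply(num_cols, function(cn)
      if (n_repeats == 1L) 0 else sd(per_repeat[[cn]]), 0))
  list(per_repeat = per_repeat, summary = agg)
}
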