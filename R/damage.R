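# Conversion of interaction events into strand breaks and DSB clustering.
#
# Per-channel break rules: DEA on a backbone molecule always breaks the
# strand; ionization breaks it when the local deposit reaches the 10 eV
# ionization threshold; electronic excitation breaks it when the deposit
# exceeds the molecule's excitation threshold; vibrational excitation and
# elastic scattering never break.  Qualifying hits on a base molecule are
# recorded as base damage, not strand breaks (no base-to-backbone charge
# transfer).  A DSB is two SSBs on opposite strands strictly fewer than
# 10 base pairs apart.

#' Break-scoring rules
#'
#' @param ionization_ssb_threshold eV; an ionization deposit at or above it
#'   on a backbone molecule is an SSB (inclusive comparison).
#' @param excitation_thresholds named eV vector per molecule kind; an
#'   electronic-excitation deposit strictly above it is an SSB (strict
#'   comparison).
#' @param dsb_max_separation base pairs; a DSB requires opposite-strand
#'   breaks with separation strictly below this.
#' @param backbone_only when TRUE (default) only backbone hits can break the
#'   strand; base hits become base-damage records.
#' @param count_dsb_constituents_in_ssb when TRUE (default) the reported SSB
#'   tally counts every accepted break, including the ones paired into DSBs.
#' @return A `damage_rules` object.
#' @export
damage_rules <- function(ionization_ssb_threshold = 10,
                         excitation_thresholds =
                           setNames(rep(10, length(MOLECULE_KINDS)),
                                    MOLECULE_KINDS),
                         dsb_max_separation = 10L,
                         backbone_only = TRUE,
                         count_dsb_constituents_in_ssb = TRUE) {
  stopifnot(ionization_ssb_threshold > 0, all(excitation_thresholds > 0),
            dsb_max_separation >= 1)
  structure(list(ionization_ssb_threshold = ionization_ssb_threshold,
                 excitation_thresholds = excitation_thresholds,
                 dsb_max_separation = as.integer(dsb_max_separation),
                 backbone_only = backbone_only,
                 count_dsb_constituents_in_ssb =
                   count_dsb_constituents_in_ssb),
            class = "damage_rules")
}

#' Score strand breaks and base damage from an event stream
#'
#' Applies the per-channel break rules to each event and collapses repeated
#' qualifying hits on the same nucleotide (one break per (target, strand,
#' bp); a broken bond cannot re-break).
#'
#' @param events event table (from [run_simulation()] or a TSV read back);
#'   needs columns channel, group, kind, strand, bp_index, target,
#'   deposit_ev, history_id.
#' @param model the `dna_model` the events refer to (bp bounds check).
#' @param rules a `damage_rules` object.
#' @return List with `breaks` (one row per accepted SSB: target, strand,
#'   bp_index, cause, history_id) and `base_damage` (same layout for
#'   qualifying base hits).
#' @export
score_breaks <- function(events, model, rules = damage_rules()) {
  ev <- as.data.table(events)
  if (!nrow(ev)) {
    empty <- data.table(target = integer(), strand = integer(),
                        bp_index = integer(), cause = character(),
                        history_id = integer())
    return(list(breaks = empty, base_damage = copy(empty)))
  }
  if (any(ev$bp_index < 1 | ev$bp_index > model$n_bp))
    stop("event bp_index outside [1, n_bp]")

  thr_exc <- rules$excitation_thresholds[ev$kind]
  qual <- (ev$channel == "dea") |
    (ev$channel == "ionization" &
       ev$deposit_ev >= rules$ionization_ssb_threshold) |
    (ev$channel == "electronic_excitation" & ev$deposit_ev > thr_exc)

  q <- ev[qual, .(target, strand, bp_index, cause = channel, history_id,
                  group)]
  if (rules$backbone_only) {
    br <- q[group == "backbone"]
    bd <- q[group == "base"]
  } else {
    br <- q
    bd <- q[0]
  }
  # collapse to one break per nucleotide, keeping the earliest event
  br <- br[!duplicated(br[, .(target, strand, bp_index)])]
  list(breaks = br[, .(target, strand, bp_index, cause, history_id)],
       base_damage = bd[, .(target, strand, bp_index, cause, history_id)])
}

#' Cluster opposite-strand breaks into double-strand breaks
#'
#' Greedy deterministic pairing: breaks are processed in ascending base-pair
#' order (per target); each unpaired break is paired with its nearest
#' unpaired opposite-strand break strictly fewer than
#' `dsb_max_separation` bp away (ties resolved toward the lower bp index).
#' Each break joins at most one DSB.  The result is independent of the input
#' row order.
#'
#' @param breaks break table from [score_breaks()] (deduplicated per
#'   nucleotide).
#' @param rules a `damage_rules` object.
#' @return `data.table` with one row per DSB: target, strand/bp/history of
#'   both breaks, `separation` (bp) and `cross_history` flag.
#' @export
cluster_dsb <- function(breaks, rules = damage_rules()) {
  br <- as.data.table(breaks)
  out <- list()
  if (!nrow(br)) return(.empty_dsb())
  setorder(br, target, bp_index, strand)
  maxsep <- rules$dsb_max_separation
  for (tgt in unique(br$target)) {
    b <- br[target == tgt]
    n <- nrow(b)
    paired <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (paired[i]) next
      cand <- which(!paired & b$strand != b$strand[i] &
                      abs(b$bp_index - b$bp_index[i]) < maxsep)
      cand <- setdiff(cand, i)
      if (!length(cand)) next
      d <- abs(b$bp_index[cand] - b$bp_index[i])
      j <- cand[order(d, b$bp_index[cand])][1]
      paired[i] <- paired[j] <- TRUE
      out[[length(out) + 1L]] <- data.table(
        target = tgt,
        strand_a = b$strand[i], bp_a = b$bp_index[i],
        history_a = b$history_id[i],
        strand_b = b$strand[j], bp_b = b$bp_index[j],
        history_b = b$history_id[j],
        separation = abs(b$bp_index[j] - b$bp_index[i]),
        cross_history = b$history_id[i] != b$history_id[j])
    }
  }
  if (!length(out)) return(.empty_dsb())
  rbindlist(out)
}

.empty_dsb <- function() {
  data.table(target = integer(), strand_a = integer(), bp_a = integer(),
             history_a = integer(), strand_b = integer(), bp_b = integer(),
             history_b = integer(), separation = integer(),
             cross_history = logical())
}

#' Exhaustive maximum matching of breaks into DSBs (oracle)
#'
#' Recursively enumerates all admissible pairings and returns the maximum
#' number of disjoint opposite-strand pairs under the separation rule.
#' Exponential; intended only as the correctness oracle for [cluster_dsb()]
#' on small inputs.
#'
#' @inheritParams cluster_dsb
#' @return Maximum attainable DSB count (integer).
#' @export
cluster_dsb_bruteforce <- function(breaks, rules = damage_rules()) {
  br <- as.data.table(breaks)
  if (!nrow(br)) return(0L)
  total <- 0L
  for (tgt in unique(br$target)) {
    b <- br[target == tgt]
    n <- nrow(b)
    adm <- outer(seq_len(n), seq_len(n), function(i, j)
      b$strand[i] != b$strand[j] &
        abs(b$bp_index[i] - b$bp_index[j]) < rules$dsb_max_separation)
    best <- function(avail) {
      i <- which(avail)[1]
      if (is.na(i)) return(0L)
      avail2 <- avail; avail2[i] <- FALSE
      # i unpaired
      m <- best(avail2)
      # i paired with any admissible j
      for (j in which(avail2 & adm[i, ])) {
        avail3 <- avail2; avail3[j] <- FALSE
        m <- max(m, 1L + best(avail3))
      }
      m
    }
    total <- total + best(rep(TRUE, n))
  }
  total
}
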