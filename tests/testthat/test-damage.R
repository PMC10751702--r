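# Break scoring rules and DSB clustering.

make_event <- function(channel, kind = "phosphate", deposit = 0,
                       strand = 1L, bp = 50L, history = 1L) {
  data.table::data.table(
    history_id = history, lineage = "primary", channel = channel,
    kind = kind, group = dnatrackmc:::molecule_group(kind),
    strand = strand, bp_index = bp, target = 1L, molecule_id = 1L,
    x = 0, y = 0, z = 0, deposit_ev = deposit, element = "P")
}

test_that("per-channel break rules match the stated thresholds", {
  m <- desk_model()
  rules <- damage_rules()

  # DEA on a phosphate: one SSB, unconditionally
  s <- score_breaks(make_event("dea", deposit = 7), m, rules)
  expect_equal(nrow(s$breaks), 1)
  expect_equal(s$breaks$cause, "dea")

  # ionization below / at the 10 eV threshold (inclusive comparison)
  s8 <- score_breaks(make_event("ionization", "deoxyribose", 8), m, rules)
  expect_equal(nrow(s8$breaks), 0)
  s10 <- score_breaks(make_event("ionization", "deoxyribose", 10), m, rules)
  expect_equal(nrow(s10$breaks), 1)

  # electronic excitation needs a deposit strictly above the threshold
  sA <- score_breaks(make_event("electronic_excitation", deposit = 10),
                     m, rules)
  expect_equal(nrow(sA$breaks), 0)
  sB <- score_breaks(make_event("electronic_excitation", deposit = 12.5),
                     m, rules)
  expect_equal(nrow(sB$breaks), 1)

  # vibrational excitation never breaks
  sv <- score_breaks(make_event("vibrational_excitation", deposit = 0.4),
                     m, rules)
  expect_equal(nrow(sv$breaks), 0)

  # qualifying hits on a base are recorded as base damage, not SSB
  sb <- score_breaks(make_event("dea", kind = "thymine", deposit = 3),
                     m, rules)
  expect_equal(nrow(sb$breaks), 0)
  expect_equal(nrow(sb$base_damage), 1)
})

test_that("repeated qualifying hits on one nucleotide collapse to one break", {
  m <- desk_model()
  ev <- rbind(make_event("dea", bp = 10L, history = 1L),
              make_event("dea", bp = 10L, history = 2L),
              make_event("ionization", deposit = 11, bp = 10L, history = 3L))
  s <- score_breaks(ev, m)
  expect_equal(nrow(s$breaks), 1)
  expect_equal(s$breaks$history_id, 1L)   # earliest event wins
  expect_error(score_breaks(make_event("dea", bp = 9999L), m), "bp_index")
})

test_that("DSB clustering follows the strict opposite-strand < 10 bp rule", {
  rules <- damage_rules()
  br <- function(strand, bp, hist = seq_along(bp)) data.table::data.table(
    target = 1L, strand = strand, bp_index = bp, cause = "dea",
    history_id = hist)

  d1 <- cluster_dsb(br(c(1L, 2L), c(100L, 105L)), rules)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$separation, 5L)
  expect_true(d1$cross_history)

  # separation exactly 10 is NOT a DSB (strict inequality)
  expect_equal(nrow(cluster_dsb(br(c(1L, 2L), c(100L, 110L)), rules)), 0)
  # same strand never pairs
  expect_equal(nrow(cluster_dsb(br(c(1L, 1L), c(100L, 101L)), rules)), 0)
  # empty input
  expect_equal(nrow(cluster_dsb(br(integer(), integer()), rules)), 0)
})

test_that("clustering is order-invariant and each break pairs at most once", {
  set.seed(31)
  for (k in 1:20) {
    b <- random_breaks(sample(3:12, 1))
    d1 <- cluster_dsb(b)
    d2 <- cluster_dsb(b[sample(nrow(b)), ])
    expect_equal(nrow(d1), nrow(d2))
    # n_ssb >= 2 * n_dsb by construction
    expect_gte(nrow(b), 2 * nrow(d1))
    # no break used twice
    used <- c(paste(d1$strand_a, d1$bp_a), paste(d1$strand_b, d1$bp_b))
    expect_equal(anyDuplicated(used), 0)
  }
})

test_that("greedy DSB counts equal the exhaustive maximum matching", {
  set.seed(41)
  gaps <- 0L
  for (k in 1:500) {
    b <- random_breaks(sample(0:12, 1))
    g <- nrow(cluster_dsb(b))
    o <- cluster_dsb_bruteforce(b)
    if (g != o) gaps <- gaps + 1L
    expect_lte(g, o)
  }
  expect_equal(gaps, 0L)
})

test_that("breaks on different targets never pair into one DSB", {
  b <- data.table::data.table(
    target = c(1L, 2L), strand = c(1L, 2L), bp_index = c(100L, 101L),
    cause = "dea", history_id = 1:2)
  expect_equal(nrow(cluster_dsb(b)), 0)
})
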