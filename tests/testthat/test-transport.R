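# Electron transport: emission, free flight, interaction physics, histories.

test_that("cone emission is monoenergetic and respects the cone geometry", {
  src <- source_config(25, c(0, 0, 0), c(0, 0, 1), half_angle = 0,
                       n_histories = 10)
  set.seed(1)
  for (k in 1:5) {
    e <- emit_primary(src)
    expect_equal(e$direction, c(0, 0, 1), tolerance = 1e-12)
    expect_identical(e$energy, 25)
  }
  # uniform cone: mean direction aligned with the axis within 3 SE
  src2 <- source_config(25, c(0, 0, 0), c(1, 0, 0), half_angle = 0.5)
  set.seed(42)
  dirs <- t(replicate(1e4, emit_primary(src2)$direction))
  expect_true(all(dirs %*% c(1, 0, 0) >= cos(0.5) - 1e-12))
  se <- apply(dirs, 2, sd) / sqrt(nrow(dirs))
  expect_lt(abs(mean(dirs[, 2])), 3 * se[2])
  expect_lt(abs(mean(dirs[, 3])), 3 * se[3])
})

test_that("flight through empty space escapes; phantom attenuation matches 1 - exp(-t/lambda)", {
  # geometry with no spheres on the ray path -> escape
  ctx <- desk_ctx()
  set.seed(3)
  fl <- fly(c(0, 150, 0), c(0, 1, 0), 10, ctx)
  expect_equal(fl$type, "escape")

  # homogeneous sphere of phosphate material, pencil beam through the centre
  lib <- build_fixture_library(elastic_only_params())
  E <- 10
  lam <- mean_free_path(lib, "phosphate", E)
  R <- lam / 2                      # chord t = 2R = lambda
  ph <- phantom_sphere(R, "phosphate")
  ctx_ph <- tracking_context(ph, library = lib, world_edge = 20 * R,
                             cell_size = R / 2)
  set.seed(4)
  n <- 2e4
  hits <- 0L
  for (i in seq_len(n)) {
    fl <- fly(c(-5 * R, 0, 0), c(1, 0, 0), E, ctx_ph)
    if (fl$type == "interaction") hits <- hits + 1L
  }
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("interaction physics follows the per-channel rules", {
  lib <- default_xsec_library()
  # elastic: zero deposit, energy unchanged, direction still unit
  set.seed(5)
  r <- do_interaction(20, c(0, 0, 1), "elastic", "phosphate", "P", lib)
  expect_equal(r$deposit, 0)
  expect_equal(r$energy, 20)
  expect_equal(sqrt(sum(r$direction^2)), 1, tolerance = 1e-12)
  expect_false(r$dead)

  # DEA: full local deposit, electron terminated
  r <- do_interaction(7, c(0, 0, 1), "dea", "phosphate", "P", lib)
  expect_equal(r$deposit, 7)
  expect_true(r$dead)
  expect_equal(r$energy, 0)

  # excitation: deposit is one permitted level, channel labelled by type
  set.seed(6)
  for (k in 1:20) {
    r <- do_interaction(8, c(0, 0, 1), "excitation", "thymine", "C", lib)
    lv <- lib$levels$thymine
    expect_true(r$deposit %in% c(lv$vibrational, lv$electronic))
    expect_lte(r$deposit, 8)
    expect_equal(r$energy, 8 - r$deposit)
    expected_ch <- if (r$deposit %in% lv$vibrational)
      "vibrational_excitation" else "electronic_excitation"
    expect_equal(r$channel, expected_ch)
  }

  # ionization of a nitrogen atom emits two Auger electrons;
  # carbon and oxygen emit one
  set.seed(7)
  r <- do_interaction(50, c(0, 0, 1), "ionization", "adenine", "N", lib)
  expect_equal(sum(vapply(r$secondaries, function(s)
    s$lineage == "auger", TRUE)), 2)
  expect_equal(sum(vapply(r$secondaries, function(s)
    s$lineage == "ionization_secondary", TRUE)), 1)
  r2 <- do_interaction(50, c(0, 0, 1), "ionization", "phosphate", "O", lib)
  expect_equal(sum(vapply(r2$secondaries, function(s)
    s$lineage == "auger", TRUE)), 1)
  # energy bookkeeping: deposit = binding, secondary <= (E - B) / 2
  B <- lib$binding[["phosphate"]]
  expect_equal(r2$deposit, B)
  eps <- r2$secondaries[[1]]$energy
  expect_lte(eps, (50 - B) / 2)
  expect_equal(r2$energy, 50 - B - eps)
})

test_that("the per-history energy ledger balances at every beam energy", {
  ctx <- desk_ctx()
  model <- desk_model()
  for (e in c(4, 20, 100)) {
    src <- source_for_model(model, e, n_histories = 300)
    sim <- run_simulation(ctx, src, seed = 11)
    expect_lt(ledger_imbalance(sim), 1e-9)
    expect_true(all(sim$ledger$E_initial == e))
  }
})

test_that("a 4 eV beam can produce neither ionization nor electronic excitation", {
  ctx <- desk_ctx()
  src <- source_for_model(desk_model(), 4, n_histories = 3000)
  sim <- run_simulation(ctx, src, seed = 13)
  spec <- interaction_spectrum(sim$events)
  expect_identical(spec[["ionization"]], 0L)
  expect_identical(spec[["electronic_excitation"]], 0L)
})

test_that("simulations are deterministic and translation invariant", {
  ctx <- desk_ctx()
  src <- source_for_model(desk_model(), 30, n_histories = 2000)
  s1 <- run_simulation(ctx, src, seed = 99)
  s2 <- run_simulation(ctx, src, seed = 99)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$ledger, s2$ledger)

  # rigid translation of the whole scene (targets + source)
  shift <- c(37, -12, 5)
  m2 <- build_bdna(200, origin = shift, seed = 1)
  ctx2 <- tracking_context(m2)
  src2 <- source_for_model(m2, 30, n_histories = 2000)
  s3 <- run_simulation(ctx2, src2, seed = 99)
  expect_identical(s3$events$channel, s1$events$channel)
  expect_identical(s3$events$molecule_id, s1$events$molecule_id)
  expect_equal(s3$events$x - shift[1], s1$events$x, tolerance = 1e-9)
  expect_equal(s3$ledger, s1$ledger)
})

test_that("interaction counts scale with the number of histories", {
  ctx <- desk_ctx()
  model <- desk_model()
  src1 <- source_for_model(model, 10, n_histories = 8000)
  src2 <- source_for_model(model, 10, n_histories = 16000)
  n1 <- nrow(run_simulation(ctx, src1, seed = 5)$events)
  n2 <- nrow(run_simulation(ctx, src2, seed = 6)$events)
  # Poisson scaling: ratio 2 within 3 SE
  se <- 2 * sqrt(1 / n1 + 1 / n2) * n2 / n1
  expect_lt(abs(n2 / n1 - 2), 3 * max(se, 0.5))

  # zero histories give an empty stream
  s0 <- run_simulation(ctx, source_for_model(model, 10, n_histories = 0),
                       seed = 1)
  expect_equal(nrow(s0$events), 0)
})

test_that("with every channel off except elastic, all histories escape with full energy", {
  lib <- build_fixture_library(elastic_only_params())
  m <- desk_model()
  ctx <- tracking_context(m, library = lib)
  src <- source_for_model(m, 50, n_histories = 500)
  sim <- run_simulation(ctx, src, seed = 21)
  expect_equal(sum(sim$ledger$E_escaped), 500 * 50)
  expect_equal(sum(sim$ledger$E_deposited), 0)
  expect_true(all(sim$events$channel == "elastic"))
})
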