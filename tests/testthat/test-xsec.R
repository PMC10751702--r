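# Cross-section tables, fixture library structure, sampling, mean free path.

test_that("interpolation is exact on nodes, linear between, zero below threshold", {
  tb <- xsec_table("phosphate", "dea", energy = c(1, 2, 3, 4),
                   sigma = c(0, 2, 4, 4), threshold = 1.5)
  expect_equal(sigma(tb, 3), 4)
  expect_equal(sigma(tb, 2.5), 3)          # midpoint of 2 and 4
  expect_equal(sigma(tb, 1.49), 0)         # just below threshold
  expect_equal(sigma(tb, 100), 4)          # clamped above the grid
  expect_error(sigma(tb, 0), "E must be > 0")
  expect_error(xsec_table("phosphate", "dea", c(1, 1, 2), c(0, 0, 0)),
               "strictly increasing")
})

test_that("fixture DEA windows honor the stated resonance locations", {
  lib <- default_xsec_library()
  E <- seq(0.2, 500, by = 0.05)
  s_ph <- sigma(lib$tables$phosphate$dea, E)
  # the phosphate DEA peak lies between 4 and 10 eV
  expect_gt(E[which.max(s_ph)], 4)
  expect_lt(E[which.max(s_ph)], 10)
  # deoxyribose DEA is confined below 3 eV
  expect_equal(max(sigma(lib$tables$deoxyribose$dea, E[E > 3])), 0)
  expect_gt(max(sigma(lib$tables$deoxyribose$dea, E[E < 2])), 0)
  # bases only attach below 4 eV
  for (k in c("adenine", "cytosine", "guanine", "thymine"))
    expect_equal(max(sigma(lib$tables[[k]]$dea, E[E > 4])), 0)
  # ionization is zero at and below 10 eV for every kind
  for (k in names(lib$tables))
    expect_equal(max(sigma(lib$tables[[k]]$ionization, c(4, 6, 10))), 0)
  # every lowest electronic excitation level is above 4 eV
  for (k in names(lib$levels))
    expect_gt(min(lib$levels[[k]]$electronic), 4)
})

test_that("zero-amplitude parameters give identically zero DEA tables", {
  p <- xsec_fixture_params()
  for (k in names(p$dea))
    p$dea[[k]]$res <- lapply(p$dea[[k]]$res, function(r) {
      r[["A"]] <- 0; r })
  lib <- build_fixture_library(p)
  for (k in names(lib$tables))
    expect_equal(max(lib$tables[[k]]$dea$sigma), 0)
})

test_that("library construction is deterministic and serializes losslessly", {
  a <- build_fixture_library()
  b <- build_fixture_library()
  expect_identical(a$tables, b$tables)

  dir <- tempfile()
  export_xsec(a, dir)
  c2 <- import_xsec(dir)
  expect_equal(c2$tables$phosphate$dea$sigma, a$tables$phosphate$dea$sigma)
  expect_equal(c2$binding, a$binding)
  expect_equal(c2$levels$thymine$electronic, a$levels$thymine$electronic)
  expect_equal(c2$number_density_nm3, a$number_density_nm3)
})

test_that("total cross-section is the channel sum and rejects mixed kinds", {
  lib <- default_xsec_library()
  tabs <- lib$tables$phosphate
  E <- c(0.5, 5, 12, 50, 400)
  tot <- total_sigma(tabs, E)
  by_hand <- sigma(tabs$elastic, E) + sigma(tabs$excitation, E) +
    sigma(tabs$ionization, E) + sigma(tabs$dea, E)
  expect_equal(tot, by_hand)
  expect_true(all(tot >= vapply(tabs, sigma, numeric(5), E = E)))
  expect_error(total_sigma(list(tabs$elastic, lib$tables$thymine$dea), E),
               "mix")
})

test_that("channel sampling follows the cross-section ratios", {
  expect_equal(unique(sample_interaction_type(c(elastic = 1, dea = 0),
                                              1000)), "elastic")
  expect_error(sample_interaction_type(c(elastic = 0, dea = 0)), "zero")

  set.seed(7)
  # 3 : 1 ratio -> frequency 0.75 within 3 binomial SE at 1e4 draws
  draws <- sample_interaction_type(c(dea = 3, excitation = 1), 1e4)
  p_hat <- mean(draws == "dea")
  se <- sqrt(0.75 * 0.25 / 1e4)
  expect_lt(abs(p_hat - 0.75), 3 * se)

  # chi-square goodness of fit on 4 channels at 1e5 draws
  w <- c(elastic = 5, excitation = 2, ionization = 1.5, dea = 0.5)
  draws <- sample_interaction_type(w, 1e5)
  obs <- table(factor(draws, levels = names(w)))
  expect_gt(stats::chisq.test(obs, p = w / sum(w))$p.value, 0.01)
})

test_that("mean free path is 1/(n sigma) and scales reciprocally", {
  libA <- build_fixture_library(elastic_only_params(2e-2))
  libB <- build_fixture_library(elastic_only_params(4e-2))
  E <- 10
  lamA <- mean_free_path(libA, "phosphate", E)
  lamB <- mean_free_path(libB, "phosphate", E)
  expect_equal(lamA / lamB, 2, tolerance = 1e-12)
  n <- libA$number_density_nm3[["phosphate"]]
  s <- sigma(libA$tables$phosphate$elastic, E)
  expect_equal(lamA, 1 / (n * s), tolerance = 1e-12)
  # n sigma = 0.1 nm^-1  ->  lambda = 10 nm
  libC <- build_fixture_library(elastic_only_params((0.1 / n) * (1 + E / 20)))
  expect_equal(mean_free_path(libC, "phosphate", E), 10, tolerance = 1e-9)
  # zero cross-section -> infinite path, not an error
  lib0 <- build_fixture_library(elastic_only_params(0))
  expect_equal(mean_free_path(lib0, "phosphate", 5), Inf)
})
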