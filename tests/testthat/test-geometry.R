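# Procedural B-DNA builder, PDB round trips, masses, phantom.

test_that("single-bp model has the canonical per-nucleotide composition", {
  m <- build_bdna(1, sequence = "A", seed = 1)
  mol <- m$molecules
  expect_equal(sum(mol$kind == "deoxyribose"), 2)
  expect_equal(sum(mol$kind == "phosphate"), 2)
  expect_equal(sum(mol$group == "base"), 2)
  # phosphate group is 1 P + 4 O spheres
  for (pid in mol[mol$kind == "phosphate", ]$molecule_id) {
    at <- m$atoms[m$atoms$molecule_id == pid, ]
    expect_equal(nrow(at), 5)
    expect_equal(sort(table(at$element), decreasing = TRUE),
                 c(O = 4L, P = 1L), ignore_attr = TRUE)
  }
  # strand 2 base is the complement
  expect_setequal(mol[mol$group == "base", ]$kind, c("adenine", "thymine"))
})

test_that("straight helix has the pinned rise and phosphates in a radial band", {
  n_bp <- 100
  m <- build_bdna(n_bp, mode = "straight", seed = 3)
  a <- merge(m$atoms, m$molecules, by = "molecule_id")
  p <- a[a$name == "P" & a$strand == 1, ]
  p <- p[order(p$bp_index), ]
  # helix-axis length = (n_bp - 1) x 0.34 nm, read off the P positions
  expect_equal(p$z[n_bp] - p$z[1], 99 * 0.34, tolerance = 1e-12)
  # helical symmetry: all P atoms at one radial distance from the z axis
  r <- sqrt(p$x^2 + p$y^2)
  expect_lt(max(r) - min(r), 1e-9)
})

test_that("condensed 1122-bp target folds to roughly 30 nm", {
  m <- build_bdna(1122, mode = "condensed", seed = 2)
  edges <- m$extent["hi", ] - m$extent["lo", ]
  expect_lt(max(edges), 30 * 1.2)
  expect_gt(max(edges), 30 * 0.8)
  # whereas straight it would be far longer than 30 nm
  expect_gt(1121 * 0.34, 300)
})

test_that("mass is the sum of standard atomic masses and is additive", {
  m <- build_bdna(2, sequence = "AT", seed = 1)
  # one phosphate group: 30.974 + 4 x 15.999 Da
  pid <- m$molecules$molecule_id[m$molecules$kind == "phosphate"][1]
  at <- m$atoms[m$atoms$molecule_id == pid, ]
  expect_equal(sum(ATOMIC_MASS_DA[at$element]), 94.970, tolerance = 1e-12)
  expect_equal(dna_mass(m), m$mass)

  # doubling n_bp with a doubled sequence doubles the mass exactly
  m1 <- build_bdna(25, sequence = "random", seed = 9)
  m2 <- build_bdna(50, sequence = paste0(m1$sequence, m1$sequence))
  expect_equal(dna_mass(m2), 2 * dna_mass(m1), tolerance = 1e-12)

  # empty model
  m0 <- m
  m0$atoms <- m0$atoms[0, ]
  expect_equal(dna_mass(m0), 0)
})

test_that("input validation rejects bad sequences and sizes", {
  expect_error(build_bdna(0), "n_bp")
  expect_error(build_bdna(3, sequence = "AXT"), "invalid base")
  expect_error(build_bdna(3, sequence = "AT"), "length")
})

test_that("PDB write/read round-trips coordinates and annotations", {
  m <- build_bdna(10, seed = 4)
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- load_pdb(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$n_bp, m$n_bp)
  expect_equal(table(m2$molecules$kind), table(m$molecules$kind))
  expect_equal(sum(m2$molecules$kind == "phosphate"), 20)
  # coordinates survive to PDB precision (1e-3 A = 1e-4 nm); compare in the
  # writer's deterministic order (strand, bp, molecule)
  a1 <- merge(m$atoms, m$molecules, by = "molecule_id")
  a1 <- a1[order(a1$strand, a1$bp_index, a1$molecule_id), ]
  expect_equal(a1$x, m2$atoms$x, tolerance = 1e-3)
  expect_equal(a1$z, m2$atoms$z, tolerance = 1e-3)
  expect_equal(a1$name, m2$atoms$name)
  expect_equal(dna_mass(m2), dna_mass(m), tolerance = 1e-12)
})

test_that("PDB loader rejects non-nucleotide residues by name", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 1, "CA", "ALA", "A", 1, 1, 1, 1, 1, 0),
    "END"), f)
  expect_error(load_pdb(f), "ALA")
})

test_that("multi-target scenes offset molecule ids and targets", {
  sc <- build_scene(n_targets = 3, n_bp = 5, spacing = 20, seed = 1)
  expect_equal(sc$n_targets, 3L)
  expect_equal(length(unique(sc$molecules$target)), 3)
  expect_equal(anyDuplicated(sc$molecules$molecule_id), 0)
  expect_equal(nrow(sc$atoms), 3 * nrow(build_bdna(5, seed = 1)$atoms))
})

test_that("phantom sphere carries one molecule of the requested material", {
  ph <- phantom_sphere(5, "deoxyribose")
  expect_equal(nrow(ph$atoms), 1)
  expect_equal(ph$atoms$radius, 5)
  expect_equal(ph$molecules$kind, "deoxyribose")
})
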