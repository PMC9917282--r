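test_that("atom distance obeys the textbook cases and metric properties", {
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    expect_equal(atom_distance(a, b), atom_distance(b, a))
    expect_lte(atom_distance(a, c),
               atom_distance(a, b) + atom_distance(b, c) + 1e-12)
  }
})

test_that("planted triad distances are measured back exactly", {
  toy <- make_toy_structure(toy_spec(og_ne2 = 3.2, nd1_od = 3.3))
  tg <- measure_triad(toy$structure, c(S = 532, D = 617, H = 652))
  expect_equal(tg$og_S_ne2_H, 3.2, tolerance = 1e-3)
  expect_equal(tg$nd1_H_od2_D, 3.3, tolerance = 1e-3)
  expect_equal(tg$nd1_H_od_min, 3.3, tolerance = 1e-3)
  expect_true(tg$assembled)
  # disassembled at large planted distances
  toy2 <- make_toy_structure(toy_spec(separation = 8))
  tg2 <- measure_triad(toy2$structure, c(S = 532, D = 617, H = 652))
  expect_false(tg2$assembled)
  expect_equal(tg2$og_S_ne2_H, toy2$truth$og_ne2, tolerance = 1e-3)
})

test_that("a Ser-mutant triad reports OG as unavailable, not an error", {
  toy <- make_toy_structure(toy_spec(mutant_S = TRUE))
  tg <- measure_triad(toy$structure, c(S = 532, D = 617, H = 652))
  expect_false(tg$og_available)
  expect_true(is.na(tg$og_S_ne2_H))
  expect_false(tg$assembled)
})

test_that("triad distances are invariant under rigid motion", {
  toy <- make_toy_structure(toy_spec())
  tg <- measure_triad(toy$structure, c(S = 532, D = 617, H = 652))
  st2 <- transform_structure(toy$structure, random_rotation(3), c(11, -4, 7))
  tg2 <- measure_triad(st2, c(S = 532, D = 617, H = 652))
  for (f in c("ca_S_H", "og_S_ne2_H", "ca_H_D", "nd1_H_od2_D"))
    expect_equal(tg2[[f]], tg[[f]], tolerance = 1e-6)
})

test_that("center-of-mass distance: point masses, rigid motion, additivity", {
  # two single-atom domains planted 25 A apart
  atoms <- data.frame(
    type = "ATOM", chain = "A", resno = c(100L, 500L), insert = "",
    resid = "ALA", elety = "CA", elesy = "C",
    x = c(0, 25), y = 0, z = 0, o = 1, b = 0, stringsAsFactors = FALSE)
  st <- new_structure(atoms)
  p <- domain_partition(st, ranges = list(propeller = c(100L, 199L),
                                          hydrolase = c(500L, 699L)))
  expect_equal(center_of_mass_distance(st, p), 25)

  toy <- make_toy_structure(toy_spec())
  d0 <- center_of_mass_distance(toy$structure, toy$partition)
  # global rigid motion leaves it unchanged
  st2 <- transform_structure(toy$structure, random_rotation(5), c(3, 3, 3))
  expect_equal(center_of_mass_distance(st2, toy$partition), d0,
               tolerance = 1e-6)
  # translating the propeller by +5 A along the exact separation axis adds
  # 5.0; the axis is computed independently from mass-weighted centroids
  mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  dom_com <- function(st, region) {
    sel <- select_residues(st, partition_residues(toy$partition, region))
    a <- st$atoms[sel, ]
    colSums(as.matrix(a[, c("x", "y", "z")]) * mass[a$elesy]) /
      sum(mass[a$elesy])
  }
  axis <- dom_com(toy$structure, "propeller") -
    dom_com(toy$structure, "catalytic")
  axis <- axis / sqrt(sum(axis^2))
  pro <- select_residues(toy$structure,
                         partition_residues(toy$partition, "propeller"))
  st3 <- transform_structure(toy$structure, translation = 5 * axis,
                             subset = pro)
  expect_equal(center_of_mass_distance(st3, toy$partition), d0 + 5,
               tolerance = 1e-6)
})

test_that("kabsch superposition: identity, rigid copy, grid-search oracle", {
  toy <- make_toy_structure(toy_spec())
  res <- residue_table(toy$structure)
  pick <- res$resno[!res$hetero][c(1, 5, 12, 20, 33, 47)]
  pairs <- data.frame(mobile = pick, target = pick)
  self <- kabsch_superpose(toy$structure, toy$structure, pairs)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  moved <- transform_structure(toy$structure, random_rotation(9), c(-8, 2, 14))
  fit <- kabsch_superpose(moved, toy$structure, pairs)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)

  # noisy 4-point set against the brute-force rotation-grid oracle
  set.seed(21)
  X <- matrix(rnorm(12, sd = 4), 4)
  Y <- X %*% t(random_rotation(22)) + matrix(rnorm(12, sd = 0.5), 4)
  svd_rmsd <- s9conf:::kabsch_fit(X, Y)$rmsd
  expect_equal(svd_rmsd, grid_rmsd_oracle(X, Y), tolerance = 1e-3)
})

test_that("collinear point sets raise a degeneracy error", {
  X <- cbind(1:5, 0, 0)
  Y <- cbind(seq(2, 10, 2), 0, 0)
  expect_error(s9conf:::kabsch_fit(X, Y), "degenerac|collinear")
})
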