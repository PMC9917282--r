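test_that("domains far apart bury nothing; closing them buries more", {
  apart <- make_toy_structure(toy_spec(separation = 10))
  im0 <- interface_metrics(apart$structure, apart$partition)
  expect_equal(unname(im0$bsa_percent), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(im0$interface_residue_percent), c(0, 0))

  closed <- make_toy_structure(toy_spec(separation = 0))
  open <- make_toy_structure(toy_spec(separation = 2))
  imc <- interface_metrics(closed$structure, closed$partition)
  imo <- interface_metrics(open$structure, open$partition)
  expect_gt(imc$bsa_percent["catalytic"], imo$bsa_percent["catalytic"])
  expect_gt(imc$bsa_percent["propeller"], imo$bsa_percent["propeller"])
  expect_true(all(unlist(imc$bsa_percent) >= 0 &
                  unlist(imc$bsa_percent) <= 100))
})

test_that("a planted Arg-Glu pair is censused as exactly one salt bridge", {
  toy <- make_toy_structure(toy_spec(network = "SB1"))
  pro <- partition_residues(toy$partition, "propeller")
  cat_ <- partition_residues(toy$partition, "catalytic")
  contacts <- find_polar_contacts(toy$structure, pro, cat_)
  sb <- contacts[contacts$kind == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_setequal(c(sb$resid1, sb$resid2), c("GLU", "ARG"))
  expect_equal(sb$distance, 3.4, tolerance = 1e-3)
})

test_that("contacts beyond the cutoffs yield an empty census", {
  # nearest cross-domain polar pair planted at 4.6 A
  atoms <- data.frame(
    type = "ATOM", chain = "A",
    resno = c(100L, 100L, 500L, 500L), insert = "",
    resid = c("SER", "SER", "SER", "SER"),
    elety = c("CA", "OG", "CA", "OG"),
    elesy = c("C", "O", "C", "O"),
    x = c(0, 1, 7.6, 5.6), y = 0, z = 0, o = 1, b = 0,
    stringsAsFactors = FALSE)
  st <- new_structure(atoms)
  contacts <- find_polar_contacts(st, 100L, 500L)
  expect_equal(nrow(contacts), 0)
})

test_that("the polar-contact census is symmetric in its two groups", {
  toy <- make_toy_structure(toy_spec(network = "RRSQ"))
  pro <- partition_residues(toy$partition, "propeller")
  cat_ <- partition_residues(toy$partition, "catalytic")
  ab <- find_polar_contacts(toy$structure, pro, cat_)
  ba <- find_polar_contacts(toy$structure, cat_, pro)
  key <- function(d) sort(paste(d$kind,
                                pmin(d$resno1, d$resno2),
                                pmax(d$resno1, d$resno2),
                                round(d$distance, 6)))
  expect_equal(key(ab), key(ba))
  expect_error(find_polar_contacts(toy$structure, pro, pro), "disjoint")
})

test_that("ligand environments honour the cutoff and grow monotonically", {
  near <- make_toy_structure(toy_spec(ligand_offset = 2))
  far <- make_toy_structure(toy_spec(ligand_offset = 60))
  expect_equal(nrow(ligand_environment(far$structure, "TCK", 4)), 0)
  expect_error(ligand_environment(near$structure, "XYZ"), "XYZ")
  prev <- -1
  for (cutoff in c(3, 3.5, 4, 4.5, 5)) {
    env <- ligand_environment(near$structure, "TCK", cutoff)
    expect_gte(nrow(env), prev)
    prev <- nrow(env)
  }
  expect_gt(prev, 0)
})
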