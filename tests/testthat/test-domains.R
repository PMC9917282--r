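test_that("the SpOpB preset places the documented hinge and covers everything", {
  p <- domain_partition(preset = "SpOpB")
  expect_equal(p$ranges$hinge1, c(71L, 77L))
  expect_equal(p$ranges$propeller, c(78L, 406L))
  expect_equal(p$ranges$hinge2, c(407L, 413L))
  all_res <- partition_residues(p, "all")
  expect_equal(all_res, 1:685)
  # catalytic = n_loop + hydrolase, disjoint from propeller
  expect_length(intersect(partition_residues(p, "catalytic"),
                          partition_residues(p, "propeller")), 0)
})

test_that("explicit intervals are echoed and validated", {
  toy <- make_toy_structure(toy_spec())
  p <- domain_partition(toy$structure,
                        ranges = list(propeller = c(100L, 199L),
                                      hydrolase = c(500L, 699L)))
  expect_equal(p$ranges$propeller, c(100L, 199L))
  expect_error(domain_partition(toy$structure,
                                ranges = list(propeller = c(100L, 550L),
                                              hydrolase = c(500L, 699L))),
               "overlap")
  expect_error(domain_partition(toy$structure,
                                ranges = list(propeller = c(100L, 199L),
                                              hydrolase = c(600L, 699L))),
               "cover")
})

test_that("TbOpB preset boundaries follow the alignment-mapped offsets", {
  p <- domain_partition(preset = "TbOpB")
  # +0 before the first insertion, +31 after the second
  expect_equal(p$ranges$hinge1, c(71L, 77L))
  expect_equal(p$ranges$propeller[2], 437L)
  expect_equal(p$ranges$hinge2, c(438L, 444L))
  expect_equal(max(partition_residues(p, "all")), 716L)
  # the E172 anchor lies inside the TbOpB propeller
  expect_true(172 %in% partition_residues(p, "propeller"))
})

test_that("self-alignment yields the identity numbering map", {
  rm <- map_numbering(reference_sequence("SpOpB"), "SpOpB")
  expect_equal(rm$map, 1:685)
  expect_equal(rm$identity, 100)
  expect_false(rm$unreliable)
  expect_equal(resolve_anchor(rm, 151L), 151L)
})

test_that("TbOpB/SpOpB anchors map to the documented positions, symmetrically", {
  fwd <- map_numbering(reference_sequence("TbOpB"), "SpOpB")
  expect_equal(fwd$map[151], 172L)
  expect_equal(fwd$map[619], 650L)
  rev <- map_numbering(reference_sequence("SpOpB"), "TbOpB")
  expect_equal(rev$map[172], 151L)
  expect_equal(rev$map[650], 619L)
  # round trip through both maps returns the original anchors
  expect_equal(rev$map[fwd$map[c(151, 619)]], c(151L, 619L))
})

test_that("planted point mutations leave the position mapping intact", {
  set.seed(42)
  x <- strsplit(reference_sequence("SpOpB"), "")[[1]]
  pos <- sample(setdiff(seq_along(x), c(150, 151, 618, 619, 621)), 10)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x[pos] <- vapply(x[pos], function(a) sample(setdiff(aa, a), 1), "")
  rm <- map_numbering(paste(x, collapse = ""), "SpOpB")
  expect_equal(rm$map, 1:685)
})

test_that("short targets are rejected and low identity flagged unreliable", {
  expect_error(map_numbering("ACDEFGHIKL", "SpOpB"), "50")
  set.seed(7)
  junk <- paste(sample(c("A", "G", "P", "W"), 600, replace = TRUE),
                collapse = "")
  rm <- map_numbering(junk, "SpOpB")
  expect_true(rm$unreliable)
})
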