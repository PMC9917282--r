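test_that("both packaged references classify into their own groups", {
  sp <- classify_sequence(reference_sequence("SpOpB"), "SpOpB")
  expect_equal(sp$group, "SpOpB_like")
  expect_equal(sp$anchor_151, "R")
  expect_equal(sp$anchor_619, "Q")
  tb <- classify_sequence(reference_sequence("TbOpB"), "TbOpB")
  expect_equal(tb$group, "TbOpB_like")
  expect_equal(tb$anchor_151, "E")
  expect_equal(tb$anchor_619, "R")
})

test_that("sequences under 500 residues are binned short without alignment", {
  frag <- substr(reference_sequence("SpOpB"), 1, 400)
  expect_equal(classify_sequence(frag)$group, "short")
  expect_error(classify_sequence("ACDEF123"), "non-amino-acid")
})

test_that("planted groups are fully recovered at low mutation rates", {
  ss <- make_sequence_set(c(SpOpB_like = 12, TbOpB_like = 12, other = 4,
                            short = 4), mutation_rate = 0, seed = 5)
  calls <- classify_sequences(ss$sequences)
  expect_equal(calls$group, ss$truth$group)

  ss2 <- make_sequence_set(c(SpOpB_like = 12, TbOpB_like = 12, other = 4,
                             short = 4), mutation_rate = 0.1, seed = 6)
  calls2 <- classify_sequences(ss2$sequences)
  expect_gte(mean(calls2$group == ss2$truth$group), 0.99)
})

test_that("tallies recover planted fractions and ignore input order", {
  ss <- make_sequence_set(c(SpOpB_like = 10, TbOpB_like = 6, other = 2,
                            short = 2), mutation_rate = 0, seed = 9)
  calls <- classify_sequences(ss$sequences)
  tal <- tally_groups(calls, ss$taxonomy, "superphylum")
  all_row <- tal[tal$taxon == "all", ]
  expect_equal(all_row$f_SpOpB_like, 0.5)
  expect_equal(all_row$f_TbOpB_like, 0.3)
  expect_equal(all_row$n_total, 20)
  # fractions per taxon sum to one
  fr <- as.matrix(tal[, paste0("f_", c("SpOpB_like", "TbOpB_like", "other",
                                       "short"))])
  expect_equal(unname(rowSums(fr)), rep(1, nrow(tal)), tolerance = 1e-9)
  # permuted input gives the same tally
  perm <- sample(nrow(calls))
  tal2 <- tally_groups(calls[perm, ], ss$taxonomy, "superphylum")
  expect_equal(tal, tal2)
})

test_that("single sequences, empty sets and unknown ranks behave", {
  one <- classify_sequences(c(x1 = reference_sequence("SpOpB")))
  tax <- data.frame(id = "x1", superphylum = "Proteobacteria",
                    phylum = "p", class = "c", order = "o")
  tal <- tally_groups(one, tax, "superphylum")
  expect_equal(tal$f_SpOpB_like[tal$taxon == "Proteobacteria"], 1)
  expect_equal(nrow(tally_groups(one[0, ], tax, "superphylum")), 0)
  expect_error(tally_groups(one, tax, "kingdom"), "superphylum")
  # ids missing from the taxonomy land in 'unassigned'
  tal3 <- tally_groups(one, tax[0, ], "superphylum")
  expect_true("unassigned" %in% tal3$taxon)
})

test_that("consensus and frequencies count columns correctly", {
  block <- c("ARSQ", "ARSQ", "ARSQ")
  cf <- consensus_and_frequencies(block)
  expect_equal(cf$consensus, "ARSQ")
  expect_true(all(apply(cf$frequencies, 1, max) == 1))

  cf2 <- consensus_and_frequencies(c("AG", "AG", "GG"))
  expect_equal(cf2$consensus, "AG")
  expect_equal(unname(cf2$frequencies["1", "A"]), 2 / 3)
  # majority gap shows as gap; minority gap is excluded from the plurality
  cf3 <- consensus_and_frequencies(c("-A", "-A", "CA"))
  expect_equal(cf3$consensus, "-A")
  expect_error(consensus_and_frequencies(c("AB", "A")), "ragged")
  expect_error(consensus_and_frequencies(c("AB", "CD"), positions = 5),
               "positions")
})

test_that("anchor columns survive mutation in group-wise consensus", {
  ss <- make_sequence_set(c(SpOpB_like = 15), mutation_rate = 0.05, seed = 13)
  cf <- consensus_and_frequencies(unname(ss$sequences),
                                  positions = c(150, 151, 618, 619, 621))
  expect_equal(cf$consensus, "RRSQQ")
})
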