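toy_state_call <- function(spec) {
  toy <- make_toy_structure(spec)
  classify_structure(toy$structure, preset = NULL, partition = toy$partition,
                     triad = c(S = 532, D = 617, H = 652),
                     refmap = toy$refmap)
}

test_that("the planted closed/intermediate/open trio is fully recovered", {
  for (st in c("closed", "intermediate", "open")) {
    cl <- toy_state_call(toy_spec(state = st))
    expect_equal(cl$state_call$state, st)
  }
})

test_that("sweeping the separation never moves the call backwards", {
  order_of <- c(closed = 1, intermediate = 2, open = 3)
  seps <- c(0, 0.3, 0.6, 0.8, 1.2, 2, 3, 5, 8, 10)
  states <- vapply(seps, function(s)
    toy_state_call(toy_spec(separation = s))$state_call$state, "")
  expect_true(all(diff(order_of[states]) >= 0))
  expect_equal(states[1], "closed")
  expect_equal(states[length(states)], "open")
  expect_true("intermediate" %in% states)
})

test_that("raising the burial threshold can only move intermediate calls to open", {
  toy <- make_toy_structure(toy_spec(state = "intermediate"))
  base <- classify_structure(toy$structure, preset = NULL,
                             partition = toy$partition,
                             triad = c(S = 532, D = 617, H = 652))
  expect_equal(base$state_call$state, "intermediate")
  strict <- classify_structure(toy$structure, preset = NULL,
                               partition = toy$partition,
                               triad = c(S = 532, D = 617, H = 652),
                               thresholds = opb_thresholds(bsa_intermediate = 50))
  expect_equal(strict$state_call$state, "open")
  # and a looser one cannot produce closed
  loose <- classify_structure(toy$structure, preset = NULL,
                              partition = toy$partition,
                              triad = c(S = 532, D = 617, H = 652),
                              thresholds = opb_thresholds(bsa_intermediate = 1))
  expect_false(loose$state_call$state == "closed")
})

test_that("Ser-mutant structures fall back to the Calpha rule with a flag", {
  cl <- toy_state_call(toy_spec(mutant_S = TRUE))
  expect_equal(cl$state_call$state, "closed")
  expect_true("mutant_inference" %in% cl$state_call$flags)
})

test_that("planted stabilization networks are classified as their modes", {
  sb1 <- make_toy_structure(toy_spec(network = "SB1"))
  m1 <- classify_stabilization_mode(sb1$structure, sb1$refmap, sb1$partition)
  expect_equal(m1$mode, "salt_bridge_SB1")
  expect_equal(unname(m1$anchors[c("propeller_151", "dloop_619")]),
               c("GLU", "ARG"))
  expect_equal(unname(m1$evidence["E/D151~R619_salt_bridge"]), 3.4,
               tolerance = 1e-3)

  rr <- make_toy_structure(toy_spec(network = "RRSQ"))
  m2 <- classify_stabilization_mode(rr$structure, rr$refmap, rr$partition)
  expect_equal(m2$mode, "complementary_surface")
  expect_equal(unname(m2$evidence["R151~Q619"]), 3.7, tolerance = 1e-3)
  expect_equal(unname(m2$evidence["S618~Q619"]), 2.6, tolerance = 1e-3)
  expect_gte(sum(m2$evidence <= 4.0), 2)

  none <- make_toy_structure(toy_spec(network = "none"))
  m3 <- classify_stabilization_mode(none$structure, none$refmap,
                                    none$partition)
  expect_equal(m3$mode, "undetermined")
})

test_that("opening the domains breaks both stabilization modes", {
  for (nw in c("SB1", "RRSQ")) {
    toy <- make_toy_structure(toy_spec(network = nw, separation = 5))
    m <- classify_stabilization_mode(toy$structure, toy$refmap,
                                     toy$partition)
    expect_equal(m$mode, "undetermined")
  }
})

test_that("unresolvable anchors raise an error and bad thresholds are rejected", {
  toy <- make_toy_structure(toy_spec(network = "SB1"))
  empty_map <- identity_refmap(positions = integer(0))
  expect_error(classify_stabilization_mode(toy$structure, empty_map,
                                           toy$partition),
               "anchors not resolvable")
  expect_error(opb_thresholds(not_a_threshold = 1), "unknown")
  expect_error(opb_thresholds(hbond = -1), "positive")
})
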