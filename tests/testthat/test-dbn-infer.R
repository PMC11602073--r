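test_that("a single slice without evidence reproduces the CPT prior", {
  dbn <- dbn_spec(list(
    dbn_node("R", c("r1", "r2"), cpt = rbind(c(0.3, 0.7))),
    dbn_node("C", c("c1", "c2"), parents = "R",
             cpt = rbind(c(0.9, 0.1), c(0.2, 0.8)))
  ))
  tr <- forward_infer(dbn, list(list()))
  p <- function(node, state) tr$probability[tr$node == node & tr$state == state]
  expect_equal(p("R", "r1"), 0.3)
  expect_equal(p("C", "c1"), 0.3 * 0.9 + 0.7 * 0.2)
})

test_that("forward filtering matches the enumeration oracle", {
  dbn <- toy_chain_dbn()
  ev <- data.frame(A = c("lo", "hi", "hi", "lo"))
  expect_lt(traj_max_diff(forward_infer(dbn, ev), enumerate_joint(dbn, ev)),
            1e-10)
  # soft evidence route
  soft <- lapply(1:3, function(i) list(A = c(0.25, 0.75)))
  expect_lt(traj_max_diff(forward_infer(dbn, soft),
                          enumerate_joint(dbn, soft)), 1e-10)
  # full bundled network over two slices
  big <- default_seagrass_dbn()
  ev2 <- data.frame(temperature = c("suboptimal", "optimal"),
                    heat_stress = c("present", "none"))
  expect_lt(traj_max_diff(forward_infer(big, ev2),
                          enumerate_joint(big, ev2)), 1e-10)
})

test_that("a two-state Markov chain matches the hand-computed filter", {
  dbn <- markov_chain_dbn(0.9, 0.8)
  tr <- forward_infer(dbn, list(list(), list()),
                      initial = list(X = c(0.6, 0.4)))
  Tm <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  f1 <- c(0.6, 0.4) %*% Tm
  f2 <- f1 %*% Tm
  expect_equal(tr$probability[tr$node == "X" & tr$slice == 1],
               as.numeric(f1), tolerance = 1e-12)
  expect_equal(tr$probability[tr$node == "X" & tr$slice == 2],
               as.numeric(f2), tolerance = 1e-12)
  # and the enumeration oracle agrees (sum over 2^3 paths)
  expect_lt(traj_max_diff(tr, enumerate_joint(dbn, list(list(), list()),
                                              initial = list(X = c(0.6, 0.4)))),
            1e-10)
})

test_that("deterministic CPTs force the trajectory", {
  dbn <- dbn_spec(list(
    dbn_node("E", c("go", "stay"), cpt = rbind(c(0.5, 0.5))),
    dbn_node("S", c("s1", "s2"), parents = "E", temporal_parents = "S",
             # go flips the state, stay keeps it
             cpt = rbind(c(0, 1),    # go,  prev s1
                         c(1, 0),    # stay, prev s1
                         c(1, 0),    # go,  prev s2
                         c(0, 1)))   # stay, prev s2
  ), evidence_nodes = "E")
  ev <- data.frame(E = c("go", "stay", "go", "go"))
  tr <- forward_infer(dbn, ev, initial = list(S = c(1, 0)))
  s2 <- tr$probability[tr$node == "S" & tr$state == "s2"]
  expect_equal(s2, c(1, 1, 0, 1), tolerance = 1e-12)
})

test_that("marginals normalise and evidence nodes are point masses", {
  dbn <- default_seagrass_dbn()
  probs <- make_monthly_probs(2030:2031, p_hs_summer = 0.5)
  ev <- sample_evidence(probs, seed = 4)
  tr <- forward_infer(dbn, ev)
  sums <- tapply(tr$probability, interaction(tr$slice, tr$node), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ev_rows <- tr[tr$node %in% c("temperature", "heat_stress"), ]
  expect_true(all(ev_rows$probability %in% c(0, 1)))
  # sampled states carry probability one
  jan_t <- ev_rows[ev_rows$node == "temperature" & ev_rows$slice == 1, ]
  expect_equal(jan_t$probability[jan_t$state == ev$temperature[1]], 1)
})

test_that("inference depends on the past only through the interface joint", {
  dbn <- default_seagrass_dbn()
  probs <- make_monthly_probs(2030, p_hs_summer = 0.6)
  ev <- sample_evidence(probs, seed = 9)
  full <- forward_infer(dbn, ev)
  joints <- attr(full, "interface_joint")
  # restart at slice 7 from the stored interface joint
  tail_run <- forward_infer(dbn, ev[7:12, ], initial = as.numeric(joints[6, ]))
  full_tail <- as.data.frame(full)[full$slice > 6, ]
  full_tail$slice <- full_tail$slice - 6L
  m <- merge(full_tail[, c("slice", "node", "state", "probability")],
             as.data.frame(tail_run)[, c("slice", "node", "state", "probability")],
             by = c("slice", "node", "state"))
  expect_lt(max(abs(m$probability.x - m$probability.y)), 1e-12)
})

test_that("inference rejects unknown nodes and states", {
  dbn <- toy_chain_dbn()
  expect_error(forward_infer(dbn, data.frame(A = "nope")), "unknown state")
  expect_error(forward_infer(dbn, data.frame(B = "b1")), "missing column")
  expect_error(forward_infer(dbn, data.frame(A = "lo"), keep_nodes = "Z"),
               "unknown node")
})

test_that("the enumeration oracle refuses oversized joint spaces", {
  dbn <- default_seagrass_dbn()
  ev <- data.frame(temperature = rep("optimal", 6),
                   heat_stress = rep("none", 6))
  expect_error(enumerate_joint(dbn, ev, cap = 1e6), "exceeding cap")
})

test_that("evidence sampling respects the monthly probabilities", {
  probs <- make_monthly_probs(2030)
  ones <- transform(probs, p_suboptimal = 1, p_heatstress = 1)
  ev1 <- sample_evidence(ones, seed = 1)
  expect_true(all(ev1$temperature == "suboptimal"))
  expect_true(all(ev1$heat_stress == "present"))
  zeros <- transform(probs, p_suboptimal = 0, p_heatstress = 0)
  ev0 <- sample_evidence(zeros, seed = 1)
  expect_true(all(ev0$temperature == "optimal"))
  expect_true(all(ev0$heat_stress == "none"))
  # empirical frequency: 10,000 monthly draws at p = 0.3
  many <- data.frame(year = 1, month = 1:10000,
                     p_suboptimal = 0.3, p_heatstress = 0.3)
  ev <- sample_evidence(many, seed = 123)
  expect_lt(abs(mean(ev$temperature == "suboptimal") - 0.3), 0.014)
  expect_lt(abs(mean(ev$heat_stress == "present") - 0.3), 0.014)
  # reproducible and seed-sensitive
  expect_identical(ev, sample_evidence(many, seed = 123))
  expect_false(identical(ev, sample_evidence(many, seed = 124)))
  # coupling rule forces sub-optimal temperature in stress months
  evc <- sample_evidence(many, seed = 5, couple_heat_to_temp = TRUE)
  expect_true(all(evc$temperature[evc$heat_stress == "present"] == "suboptimal"))
  # missing probabilities -> error
  na_probs <- transform(probs, p_heatstress = NA)
  expect_error(sample_evidence(na_probs, seed = 1), "without probabilities")
})
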