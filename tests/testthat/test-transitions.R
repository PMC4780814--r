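test_that("transition counting respects sequence boundaries", {
  m1 <- build_transition_model(list(c("ST", "GPR", "TLK", "OLK")))
  expect_equal(m1$probs["ST", "GPR"], 1)
  expect_equal(m1$probs["GPR", "TLK"], 1)
  expect_equal(m1$probs["TLK", "OLK"], 1)
  expect_true("OLK" %in% m1$zero_rows)

  m2 <- build_transition_model(list(c("A", "B"), c("A", "C")))
  expect_equal(m2$probs["A", "B"], 0.5)
  expect_equal(m2$probs["A", "C"], 0.5)

  m3 <- build_transition_model(list(c("A", "B"), c("B", "A")))
  expect_equal(m3$counts["A", "B"], 1L)
  expect_equal(m3$counts["B", "A"], 1L)
  expect_equal(m3$counts["B", "B"], 0L)   # no transition across the boundary

  expect_error(build_transition_model(list(c("A", "X")), states = c("A", "B")),
               "outside state set")
})

test_that("virtual endpoint states capture entries and exits", {
  m <- build_transition_model(list(c("A", "B"), c("A", "B")),
                              include_virtual = TRUE)
  expect_equal(m$probs["START", "A"], 1)
  expect_equal(m$probs["B", "END"], 1)
  expect_equal(m$n_transitions, 6)
})

test_that("counts are additive over concatenated sequence sets", {
  set.seed(91)
  alph <- c("ST", "GPR", "TLK", "OLK", "IMS")
  rand_seqs <- function(n) {
    replicate(n, sample(alph, sample(2:8, 1), replace = TRUE),
              simplify = FALSE)
  }
  s1 <- rand_seqs(10); s2 <- rand_seqs(7)
  m1 <- build_transition_model(s1, alph)
  m2 <- build_transition_model(s2, alph)
  m12 <- build_transition_model(c(s1, s2), alph)
  expect_equal(m12$counts, m1$counts + m2$counts)
})

test_that("Hellinger distance matches closed-form values and its axioms", {
  expect_equal(hellinger(c(.3, .7), c(.3, .7)), 0)
  expect_equal(hellinger(c(1, 0), c(0, 1)), 1)
  expect_equal(hellinger(c(1, 0), c(0, 1), "unnormalized"), sqrt(2))
  expect_equal(hellinger(c(.5, .5), c(.25, .75)), 0.1845919, tolerance = 1e-6)
  expect_error(hellinger(c(1, 0), c(1, 0, 0)), "dimension")
  expect_error(hellinger(c(.5, .4), c(.5, .5)), "sum to 1")
  expect_true(is.na(hellinger(c(0, 0), c(1, 0))))

  set.seed(14)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    q <- rgamma(k, 1); q <- q / sum(q)
    d <- hellinger(p, q)
    expect_equal(d, hellinger(q, p))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_lte(hellinger(p, q, "unnormalized"), sqrt(2))
    expect_equal(hellinger(p, p), 0)
  }
})

test_that("conditional entropy attains its bounds exactly and matches the summation oracle", {
  det <- build_transition_model(list(rep(c("A", "B", "C"), 20)),
                                states = c("A", "B", "C"))
  expect_equal(conditional_entropy(det), 0)

  # uniform rows over 4 states with uniform marginal: H = log2(4) = 2 bits
  set.seed(6)
  unif <- build_transition_model(
    list(as.character(sample(4, 40000, replace = TRUE))),
    states = as.character(1:4))
  h <- conditional_entropy(unif)
  expect_lt(abs(h - 2), 0.01)
  exact_unif <- structure(list(
    states = c("A", "B"), counts = matrix(1L, 2, 2),
    probs = matrix(.5, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))),
    source_marginal = c(A = .5, B = .5), zero_rows = character(0),
    n_transitions = 4L, include_virtual = FALSE), class = "transition_model")
  expect_equal(conditional_entropy(exact_unif), 1)

  # frozen from the direct-summation oracle
  P <- matrix(c(.5, .5, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  mod <- structure(list(states = c("A", "B"), counts = matrix(1L, 2, 2),
                        probs = P, source_marginal = c(A = .5, B = .5),
                        zero_rows = character(0), n_transitions = 4L,
                        include_virtual = FALSE), class = "transition_model")
  expect_equal(conditional_entropy(mod, 2), 0.5)
  expect_equal(conditional_entropy(mod, 2), centropy_oracle(P, c(.5, .5)))
  expect_equal(conditional_entropy(mod, exp(1)), 0.5 * log(2))

  # bounds on random models
  set.seed(15)
  for (i in 1:10) {
    seqs <- replicate(8, sample(c("A", "B", "C"), 10, replace = TRUE),
                      simplify = FALSE)
    m <- build_transition_model(seqs, c("A", "B", "C"))
    h <- conditional_entropy(m)
    expect_gte(h, 0)
    expect_lte(h, log2(3) + 1e-12)
  }
  expect_error(conditional_entropy(build_transition_model(list())), "no transitions")
})

test_that("flow comparison is zero for identical groups and tracks generating rows", {
  gen <- generate_dataset(n_expert_surgeons = 3, n_novice_surgeons = 3,
                          trials_per_surgeon = 10, seed = 19)
  groups <- split_by_skill(gen$dataset, "experience")
  same <- compare_flows(groups$expert, groups$expert, "maneuver",
                        n_boot = 50, seed = 1)
  expect_true(all(same$hellinger[!is.na(same$hellinger)] == 0))

  # large sample: empirical per-state distances approach the profile rows'
  p <- default_profiles()
  big <- generate_dataset(n_expert_surgeons = 10, n_novice_surgeons = 10,
                          trials_per_surgeon = 30, seed = 23)
  gb <- split_by_skill(big$dataset, "experience")
  states <- c("ST", "GPR", "TLK", "OLK", "IMS")
  me <- build_transition_model(lapply(gb$expert, maneuver_sequence),
                               states, include_virtual = TRUE)
  mn <- build_transition_model(lapply(gb$novice, maneuver_sequence),
                               states, include_virtual = TRUE)
  for (s in states) {
    truth <- hellinger(p$expert$maneuver_transitions[s, ],
                       p$novice$maneuver_transitions[s, ])
    est <- hellinger(me$probs[s, c(states, "END")] /
                       sum(me$probs[s, c(states, "END")]),
                     mn$probs[s, c(states, "END")] /
                       sum(mn$probs[s, c(states, "END")]))
    expect_lt(abs(est - truth), 0.08)
  }
})

test_that("entropy difference separates deterministic from uniform task flow", {
  det_seqs <- replicate(40, rep(c("A", "B", "C", "D"), 5), simplify = FALSE)
  set.seed(31)
  unif_seqs <- replicate(40, sample(c("A", "B", "C", "D"), 25, replace = TRUE),
                         simplify = FALSE)
  mk_trials <- function(seqs) lapply(seq_along(seqs), function(i) {
    vocabless_trial(i, seqs[[i]])
  })
  # identical groups: difference exactly zero
  ta <- mk_trials(det_seqs)
  d0 <- entropy_difference(ta, ta, "maneuver", n_boot = 30, seed = 2)
  expect_equal(d0$difference, 0)

  d <- entropy_difference(mk_trials(det_seqs), mk_trials(unif_seqs),
                          "maneuver", n_boot = 50, seed = 3, log_base = 2)
  expect_lt(abs(d$difference - (-2)), 0.05)   # -log2(4)
  expect_lt(d$bi_high, 0)
})

test_that("DOT export is deterministic and honours the edge threshold", {
  m <- build_transition_model(list(c("A", "B", "C"), c("A", "B", "C")))
  dot <- export_stateflow_dot(m)
  expect_identical(dot, export_stateflow_dot(m))
  expect_equal(length(grep("->", strsplit(dot, "\n")[[1]])), 2)
  expect_match(dot, "\"A\" -> \"B\" \\[penwidth=5.00")

  skew <- build_transition_model(c(replicate(9, c("A", "B"), simplify = FALSE),
                                   list(c("A", "C"))))
  full <- export_stateflow_dot(skew, min_edge_fraction = 0)
  cut <- export_stateflow_dot(skew, min_edge_fraction = 0.2)
  expect_match(full, "\"A\" -> \"C\"")
  expect_no_match(cut, "\"A\" -> \"C\"")
  expect_match(cut, "\"A\" -> \"B\"")
})
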