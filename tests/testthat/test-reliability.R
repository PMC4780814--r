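test_that("edit distance matches worked examples and handles strings", {
  expect_equal(levenshtein("robots", "robust"), 3)
  expect_equal(levenshtein("kitten", "sitting"), 3)
  expect_equal(levenshtein(c("ST", "GPR", "TLK"), c("ST", "GPR", "TLK")), 0)
  expect_equal(levenshtein(character(0), c("A", "B")), 2)
})

test_that("edit distance agrees with the recursive oracle and obeys metric axioms", {
  set.seed(404)
  alphabet <- c("a", "b", "c")
  rand_seq <- function() sample(alphabet, sample(0:6, 1), replace = TRUE)
  for (i in 1:40) {
    a <- rand_seq(); b <- rand_seq(); c <- rand_seq()
    d_ab <- levenshtein(a, b)
    expect_equal(d_ab, lev_oracle(a, b))
    if (length(a) && length(b)) {
      expect_equal(d_ab, as.integer(utils::adist(paste(a, collapse = ""),
                                                 paste(b, collapse = ""))))
    }
    expect_equal(d_ab, levenshtein(b, a))                       # symmetry
    expect_equal(levenshtein(a, a), 0)                          # identity
    expect_lte(d_ab, levenshtein(a, c) + levenshtein(c, b))     # triangle
    expect_lte(d_ab, max(length(a), length(b)))                 # bound
  }
  # prefix relation attains the length-difference lower bound
  expect_equal(levenshtein(c("x", "y"), c("x", "y", "z", "w")), 2)
})

test_that("normalisation divides by the designated reference per 10 labels", {
  a <- rep("A", 10); b <- c(rep("A", 7), "B", "C", "D")
  expect_equal(normalized_ld_per10(a, b), 3.0)
  expect_equal(normalized_ld_per10(a, a), 0.0)
  expect_equal(normalized_ld_per10(rep("A", 20), c(rep("A", 18), "B", "B")), 1.0)
  expect_error(normalized_ld_per10(a, character(0)), "empty")
  # reference switch changes the denominator
  expect_equal(normalized_ld_per10(c("A", "B"), c("A", "B", "C", "D"),
                                   reference = "a"), 10)
  expect_equal(normalized_ld_per10(c("A", "B"), c("A", "B", "C", "D"),
                                   reference = "b"), 5)
})

test_that("mean LD across trials has sane degenerate and calibrated behaviour", {
  seqs <- replicate(5, c("ST", "GPR", "TLK", "OLK"), simplify = FALSE)
  r <- mean_ld_with_ci(seqs, seqs, n_boot = 200, seed = 1)
  expect_equal(r$mean_nld, 0)
  expect_equal(c(r$ci_low, r$ci_high), c(0, 0))

  one <- mean_ld_with_ci(seqs[1], seqs[1], n_boot = 200, seed = 1)
  expect_false(one$ci_available)

  # substitution-only corruption at rate 0.1 on length-100 sequences:
  # expected normalised LD is 10 * 0.1 = 1 per 10 labels
  set.seed(77)
  ref <- replicate(50, sample(c("A", "B", "C", "D"), 100, replace = TRUE),
                   simplify = FALSE)
  cor <- lapply(ref, corrupt_sequence, substitution_rate = 0.1,
                alphabet = c("A", "B", "C", "D"))
  r2 <- mean_ld_with_ci(cor, ref, n_boot = 200, seed = 2)
  expect_lt(abs(r2$mean_nld - 1.0), 0.15)
})

test_that("frame kappa reproduces hand-computed confusion-table cases", {
  expect_equal(frame_kappa(c("A", "A", "B", "B"), c("A", "A", "B", "B"))$kappa, 1)
  expect_equal(frame_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))$kappa, 0)
  expect_equal(frame_kappa(c("A", "A", "B", "B"), c("B", "B", "A", "A"))$kappa, -1)
  expect_error(frame_kappa(c("A", "B"), c("A")), "length")
  # single constant shared label: agreement is perfect but chance-corrected
  # agreement is undefined; defined as 1 for identical tracks
  expect_equal(frame_kappa(c("A", "A"), c("A", "A"))$kappa, 1)
})

test_that("kappa is invariant under bijective relabeling and near zero for independent tracks", {
  set.seed(505)
  for (i in 1:10) {
    t1 <- sample(c("A", "B", "C"), 200, replace = TRUE, prob = c(.5, .3, .2))
    t2 <- sample(c("A", "B", "C"), 200, replace = TRUE, prob = c(.2, .5, .3))
    k <- frame_kappa(t1, t2)$kappa
    ren <- c(A = "X", B = "Y", C = "Z")
    expect_equal(frame_kappa(unname(ren[t1]), unname(ren[t2]))$kappa, k)
  }
  ks <- replicate(30, {
    frame_kappa(sample(c("A", "B", "C"), 2000, replace = TRUE),
                sample(c("A", "B", "C"), 2000, replace = TRUE))$kappa
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("per-category kappa pools frames across trials", {
  a <- list(frame_track(c("A", "A", "B"), "x", "left"),
            frame_track(c("B", "B"), "x", "left"),
            frame_track(c("C", "C"), "x", "camera"))
  b <- list(frame_track(c("A", "A", "B"), "y", "left"),
            frame_track(c("B", "A"), "y", "left"),
            frame_track(c("C", "C"), "y", "camera"))
  r <- kappa_by_category(a, b)
  expect_setequal(r$pooled$category, c("left", "camera"))
  expect_equal(r$pooled$n_frames[r$pooled$category == "left"], 5)
  expect_equal(r$pooled$kappa[r$pooled$category == "camera"], 1)
  expect_equal(nrow(r$per_trial), 3)
  # category mismatch between paired tracks is an error
  expect_error(frame_kappa(frame_track("A", "x", "left"),
                           frame_track("A", "y", "right")), "categor")
})
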