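#' Skill-conditioned generative profile
#'
#' A profile holds everything needed to simulate annotated trials for one
#' skill class: a first-order Markov chain over the five collapsed maneuvers
#' with virtual `START`/`END` states, a gesture chain per maneuver over that
#' maneuver's gesture subset, per-gesture Bernoulli error and per-maneuver
#' incomplete rates, a log-normal frame-duration model (video at 30 fps), and
#' the skill class its GRS item scores are sampled to be consistent with.
#'
#' Transition matrices are stored with rows `START` plus the states and
#' columns the states plus `END`; every row must sum to 1.
#'
#' @param label Class label (`expert`, `novice`, `intermediate`).
#' @param maneuver_transitions Stochastic matrix over the collapsed maneuvers.
#' @param gesture_transitions Named list (by collapsed maneuver) of stochastic
#'   matrices over that maneuver's gesture subset.
#' @param gesture_error_rate Bernoulli error probability per gesture.
#' @param incomplete_rate Bernoulli incomplete probability per maneuver.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of gesture
#'   frame counts.
#' @return A `skill_profile`.
#' @export
skill_profile <- function(label, maneuver_transitions, gesture_transitions,
                          gesture_error_rate, incomplete_rate,
                          duration_meanlog = log(40), duration_sdlog = 0.35) {
  check_chain(maneuver_transitions)
  for (g in gesture_transitions) check_chain(g)
  stopifnot(gesture_error_rate >= 0, gesture_error_rate <= 1,
            incomplete_rate >= 0, incomplete_rate <= 1)
  structure(list(label = label,
                 maneuver_transitions = maneuver_transitions,
                 gesture_transitions = gesture_transitions,
                 gesture_error_rate = gesture_error_rate,
                 incomplete_rate = incomplete_rate,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog),
            class = "skill_profile")
}

check_chain <- function(P) {
  if (!is.matrix(P) || is.null(rownames(P)) || is.null(colnames(P))) {
    stop("transition matrices need row and column names")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("profile rows must be stochastic (non-negative, summing to 1)")
  }
  invisible(P)
}

# chain matrix from a canonical gesture path: at step i the surgeon inserts an
# adjustment (AD) with prob `ad`, repeats the step with prob `rep_`, otherwise
# advances; AD returns uniformly to the path steps (small self-loop and exit)
path_chain <- function(path, ad, rep_) {
  steps <- unique(path)
  states <- c(steps, "AD")
  P <- matrix(0, length(states) + 1, length(states) + 1,
              dimnames = list(c("START", states), c(states, "END")))
  P["START", path[1]] <- 1
  k <- length(path)
  for (i in seq_len(k)) {
    row <- stats::setNames(numeric(length(states) + 1), c(states, "END"))
    row["AD"] <- ad
    row[path[i]] <- row[path[i]] + rep_
    nxt <- if (i < k) path[i + 1] else "END"
    row[nxt] <- row[nxt] + (1 - ad - rep_)
    P[path[i], ] <- row
  }
  P["AD", "AD"] <- 0.10
  P["AD", steps] <- P["AD", steps] + 0.85 / length(steps)
  P["AD", "END"] <- 0.05
  P
}

# single-state AD chain with self-loop p => expected length 1/(1-p)
ims_chain <- function(expected_length) {
  p <- 1 - 1 / expected_length
  matrix(c(1, 0, p, 1 - p), 2, 2, byrow = TRUE,
         dimnames = list(c("START", "AD"), c("AD", "END")))
}

#' Default expert and novice profiles
#'
#' The expert maneuver chain follows the canonical task order (suture throw,
#' grasp-pull-run, two-loop knot, one-loop knot) interleaved with
#' inter-maneuver segments and has no direct `TLK`->`OLK` or `OLK`->`OLK`
#' edges; the novice chain adds low-probability repeat and backtrack edges
#' (including `OLK`->`OLK` and `TLK`->`OLK`, observed only in novice trials)
#' and uses more adjustment gestures within maneuvers. The chains are
#' phase-progressive (detours through the inter-maneuver segment are short)
#' and calibrated so the analytic absorbing-chain expectations of total
#' gestures per trial are 26.31 (expert) and 31.30 (novice); per-gesture
#' error rates are then set so the expected error-gesture counts are exactly
#' 1.00 and 2.84.
#'
#' @return Named list with `expert` and `novice` [skill_profile()]s.
#' @export
default_profiles <- function() {
  man <- c("ST", "GPR", "TLK", "OLK", "IMS")
  Pe <- matrix(0, 6, 6, dimnames = list(c("START", man), c(man, "END")))
  Pe["START", "ST"] <- 1
  Pe["ST", c("GPR", "IMS")] <- c(.72, .28)
  Pe["GPR", c("TLK", "IMS")] <- c(.72, .28)
  Pe["TLK", "IMS"] <- 1
  Pe["OLK", c("IMS", "END")] <- c(.10, .90)
  Pe["IMS", c("ST", "GPR", "TLK", "OLK", "END")] <- c(.02, .14, .16, .60, .08)

  Pn <- matrix(0, 6, 6, dimnames = list(c("START", man), c(man, "END")))
  Pn["START", "ST"] <- 1
  Pn["ST", c("ST", "GPR", "IMS")] <- c(.05, .60, .35)
  Pn["GPR", c("GPR", "TLK", "IMS")] <- c(.07, .58, .35)
  Pn["TLK", c("TLK", "OLK", "IMS")] <- c(.07, .07, .86)
  Pn["OLK", c("TLK", "OLK", "IMS", "END")] <- c(.05, .07, .16, .72)
  Pn["IMS", c("ST", "GPR", "TLK", "OLK", "END")] <-
    c(.04, .15, .18, .53, .10)

  gest_e <- list(
    ST  = path_chain(c("GN", "DN", "RN", "PN"), .197, .105),
    GPR = path_chain(c("GN", "PN"), .197, .105),
    TLK = path_chain(c("LS", "GT", "PT", "TK"), .197, .105),
    OLK = path_chain(c("LS", "GT", "PT", "TK"), .197, .105),
    IMS = ims_chain(2.00)
  )
  gest_n <- list(
    ST  = path_chain(c("GN", "DN", "RN", "PN"), .22, .115),
    GPR = path_chain(c("GN", "PN"), .22, .115),
    TLK = path_chain(c("LS", "GT", "PT", "TK"), .22, .115),
    OLK = path_chain(c("LS", "GT", "PT", "TK"), .22, .115),
    IMS = ims_chain(2.13)
  )

  expert <- skill_profile("expert", Pe, gest_e, 0, .02)
  novice <- skill_profile("novice", Pn, gest_n, 0, .10)
  # error rates chosen so expected error counts hit 1.00 and 2.84 exactly
  expert$gesture_error_rate <- 1.00 / expected_profile_stats(expert)$expected_gestures
  novice$gesture_error_rate <- 2.84 / expected_profile_stats(novice)$expected_gestures
  list(expert = expert, novice = novice)
}

#' Mix two profiles into an intermediate one
#'
#' Element-wise even mixture of transition matrices and rates; used as the
#' default intermediate skill class.
#'
#' @param a,b `skill_profile`s with identical state structure.
#' @param label Label of the mixture.
#' @return A `skill_profile`.
#' @export
mix_profiles <- function(a, b, label = "intermediate") {
  gest <- stats::setNames(lapply(names(a$gesture_transitions), function(M) {
    (a$gesture_transitions[[M]] + b$gesture_transitions[[M]]) / 2
  }), names(a$gesture_transitions))
  skill_profile(label,
                (a$maneuver_transitions + b$maneuver_transitions) / 2,
                gest,
                (a$gesture_error_rate + b$gesture_error_rate) / 2,
                (a$incomplete_rate + b$incomplete_rate) / 2,
                (a$duration_meanlog + b$duration_meanlog) / 2,
                (a$duration_sdlog + b$duration_sdlog) / 2)
}

#' Analytic expectations implied by a profile
#'
#' Closed-form absorbing-Markov-chain expectations: expected visits to each
#' maneuver per trial (`start %*% (I - Q)^{-1}`), expected gestures per
#' maneuver instance, and the derived expected total maneuvers, gestures and
#' error gestures per trial.
#'
#' @param profile A `skill_profile`.
#' @return List with `maneuver_visits`, `gestures_per_instance`,
#'   `expected_maneuvers`, `expected_gestures`, `expected_error_gestures`.
#' @export
expected_profile_stats <- function(profile) {
  visits <- chain_expected_visits(profile$maneuver_transitions)
  per_instance <- vapply(profile$gesture_transitions, function(P) {
    sum(chain_expected_visits(P))
  }, numeric(1))
  per_instance <- per_instance[names(visits)]
  eg <- sum(visits * per_instance)
  list(maneuver_visits = visits,
       gestures_per_instance = per_instance,
       expected_maneuvers = sum(visits),
       expected_gestures = eg,
       expected_error_gestures = eg * profile$gesture_error_rate)
}

chain_expected_visits <- function(P) {
  states <- setdiff(rownames(P), "START")
  Q <- P[states, states, drop = FALSE]
  start <- P["START", states]
  v <- as.vector(start %*% solve(diag(length(states)) - Q))
  stats::setNames(v, states)
}

sample_chain <- function(P, max_len = 500) {
  states <- colnames(P)
  cur <- "START"
  out <- character(0)
  while (length(out) < max_len) {
    cur <- sample(states, 1, prob = P[cur, ])
    if (cur == "END") break
    out <- c(out, cur)
  }
  out
}

#' Generate a synthetic annotated dataset with known ground truth
#'
#' Simulates the study's data shape: expert and novice surgeons each perform
#' several trials (the defaults, 4 + 14 surgeons with 8 and 7 trials
#' alternating, yield 135 trials). Each trial samples a maneuver sequence
#' from the class's chain, a gesture sequence per maneuver instance from the
#' maneuver's chain, Bernoulli error and incomplete flags, log-normal gesture
#' durations tiling each maneuver span (maneuvers abut on the frame axis),
#' and six GRS item scores consistent with the class under all three GRS
#' definitions (rejection sampling). The result is assembled through
#' [assemble_dataset()], so it satisfies every type invariant by
#' construction.
#'
#' @param n_expert_surgeons,n_novice_surgeons Surgeon counts.
#' @param trials_per_surgeon Integer vector recycled over surgeons.
#' @param profiles List with `expert` and `novice` [skill_profile()]s.
#' @param seed Integer seed; fixed seed gives a byte-identical dataset.
#' @return List with `dataset` (a `surg_dataset`; each trial carries its
#'   `surgeon_id`) and `ground_truth` (profiles, seed, and the per-trial
#'   surgeon/class map).
#' @export
generate_dataset <- function(n_expert_surgeons = 4, n_novice_surgeons = 14,
                             trials_per_surgeon = c(8, 7),
                             profiles = default_profiles(), seed = 1) {
  stopifnot(n_expert_surgeons >= 0, n_novice_surgeons >= 0)
  set.seed(seed)
  surgeons <- data.frame(
    surgeon_id = c(sprintf("E%02d", seq_len(n_expert_surgeons)),
                   sprintf("N%02d", seq_len(n_novice_surgeons))),
    class = rep(c("expert", "novice"),
                c(n_expert_surgeons, n_novice_surgeons)),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(surgeons)
  if (n_s == 0) {
    empty_skills <- data.frame(trial_id = integer(),
                               experience_class = integer(),
                               grs_total = integer())
    empty <- assemble_dataset(tab_empty_gestures(), tab_empty_maneuvers(),
                              empty_skills)
    return(list(dataset = empty,
                ground_truth = list(profiles = profiles, seed = seed,
                                    trials = data.frame())))
  }
  n_trials <- rep_len(as.integer(trials_per_surgeon), n_s)

  man_rows <- list(); ges_rows <- list(); skill_rows <- list()
  truth_rows <- list()
  tid <- 0L
  man_global_row <- 0L
  for (si in seq_len(n_s)) {
    prof <- profiles[[surgeons$class[si]]]
    for (k in seq_len(n_trials[si])) {
      tid <- tid + 1L
      mseq <- sample_chain(prof$maneuver_transitions, max_len = 60)
      frame <- 0L
      for (mi in seq_along(mseq)) {
        M <- mseq[mi]
        gseq <- sample_chain(prof$gesture_transitions[[M]])
        if (length(gseq) == 0) gseq <- "AD"  # a maneuver has >= 1 gesture
        dur <- pmax(1L, as.integer(round(stats::rlnorm(
          length(gseq), prof$duration_meanlog, prof$duration_sdlog))))
        g_end <- frame + cumsum(dur)
        g_start <- c(frame, g_end[-length(g_end)])
        man_global_row <- man_global_row + 1L
        man_rows[[man_global_row]] <- data.frame(
          trial_id = tid, label_raw = raw_variant(M),
          incomplete = stats::runif(1) < prof$incomplete_rate,
          start_frame = frame, end_frame = g_end[length(g_end)],
          stringsAsFactors = FALSE)
        ges_rows[[length(ges_rows) + 1L]] <- data.frame(
          trial_id = tid, label = gseq,
          error = stats::runif(length(gseq)) < prof$gesture_error_rate,
          maneuver_row = man_global_row,
          start_frame = g_start, end_frame = g_end,
          stringsAsFactors = FALSE)
        frame <- g_end[length(g_end)]
      }
      items <- sample_grs_items(surgeons$class[si])
      skill_rows[[tid]] <- data.frame(
        trial_id = tid,
        experience_class = if (surgeons$class[si] == "expert") 1L else 0L,
        grs_total = sum(items),
        grs1 = items[1], grs2 = items[2], grs3 = items[3],
        grs4 = items[4], grs5 = items[5], grs6 = items[6])
      truth_rows[[tid]] <- data.frame(
        trial_id = tid, surgeon_id = surgeons$surgeon_id[si],
        class = surgeons$class[si], stringsAsFactors = FALSE)
    }
  }
  maneuvers <- do.call(rbind, man_rows)
  maneuvers$ordinal <- ordinal_within(maneuvers$trial_id)
  maneuvers$label_collapsed <- sub("_[LR]$", "", maneuvers$label_raw)
  gestures <- do.call(rbind, ges_rows)
  gestures$ordinal <- ordinal_within(gestures$trial_id)
  skills <- do.call(rbind, skill_rows)
  truth <- do.call(rbind, truth_rows)

  ds <- assemble_dataset(gestures, maneuvers, skills, default_vocabulary())
  for (i in seq_len(nrow(truth))) {
    ds$trials[[as.character(truth$trial_id[i])]]$surgeon_id <- truth$surgeon_id[i]
  }
  list(dataset = ds,
       ground_truth = list(profiles = profiles, seed = seed, trials = truth))
}

# TLK/OLK have left/right raw variants; pick one uniformly
raw_variant <- function(M) {
  if (M %in% c("TLK", "OLK")) paste0(M, sample(c("_L", "_R"), 1)) else M
}

# GRS item scores consistent with the class under all three GRS definitions
sample_grs_items <- function(class) {
  if (class == "expert") {
    return(sample(4:5, 6, replace = TRUE))
  }
  if (class == "novice") {
    repeat {
      it <- sample(1:3, 6, replace = TRUE, prob = c(.40, .45, .15))
      if (sum(it) < 14 && sum(it >= 3) <= 2) return(it)
    }
  }
  repeat {  # intermediate under all three definitions
    it <- sample(2:4, 6, replace = TRUE, prob = c(.3, .4, .3))
    tot <- sum(it)
    if (tot >= 14 && tot <= 22 &&
        classify_grs2(it) == "intermediate" &&
        classify_grs3(it) == "intermediate") return(it)
  }
}

#' Corrupt a label sequence with independent editing events
#'
#' Emulates a second annotator: each position is deleted with probability
#' `deletion_rate`, otherwise substituted (by a different label drawn from
#' `alphabet`) with probability `substitution_rate`; after each original
#' position a random label is inserted with probability `insertion_rate`.
#'
#' @param labels Character vector.
#' @param substitution_rate,insertion_rate,deletion_rate Rates in `[0, 1]`.
#' @param alphabet Labels to draw substitutions/insertions from; defaults to
#'   the labels present in the sequence.
#' @param seed Optional integer seed.
#' @return Character vector (possibly empty).
#' @export
corrupt_sequence <- function(labels, substitution_rate = 0,
                             insertion_rate = 0, deletion_rate = 0,
                             alphabet = unique(labels), seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            insertion_rate >= 0, insertion_rate <= 1,
            deletion_rate >= 0, deletion_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  for (l in labels) {
    if (stats::runif(1) >= deletion_rate) {
      if (stats::runif(1) < substitution_rate && length(alphabet) > 1) {
        l <- sample(setdiff(alphabet, l), 1)
      }
      out <- c(out, l)
    }
    if (stats::runif(1) < insertion_rate) {
      out <- c(out, sample(alphabet, 1))
    }
  }
  out
}

#' Second-annotator version of a trial
#'
#' Applies [corrupt_sequence()] editing events to the trial's gesture events
#' (insertions split the current event's span in half) and jitters internal
#' gesture boundaries uniformly within `±boundary_jitter_frames`, preserving
#' order; events whose span collapses to zero length are deleted and
#' counted.
#'
#' @param trial A `surg_trial` with frame spans.
#' @param substitution_rate,insertion_rate,deletion_rate Editing rates.
#' @param boundary_jitter_frames Maximum absolute boundary shift in frames.
#' @param vocabulary Vocabulary supplying the substitution alphabet (labels
#'   observed in the trial are used when `NULL`).
#' @param seed Optional integer seed.
#' @return List with `trial` (the corrupted `surg_trial`) and `n_dropped`
#'   (events removed because their span collapsed).
#' @export
corrupt_annotation <- function(trial, substitution_rate = 0,
                               insertion_rate = 0, deletion_rate = 0,
                               boundary_jitter_frames = 0,
                               vocabulary = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- trial$gestures
  alphabet <- if (is.null(vocabulary)) unique(g$label) else
    vocabulary$gestures$label[1:9]
  rows <- list()
  for (i in seq_len(nrow(g))) {
    if (stats::runif(1) < deletion_rate) next
    lab <- g$label[i]
    if (stats::runif(1) < substitution_rate && length(alphabet) > 1) {
      lab <- sample(setdiff(alphabet, lab), 1)
    }
    if (stats::runif(1) < insertion_rate && g$end_frame[i] - g$start_frame[i] >= 2) {
      mid <- g$start_frame[i] + (g$end_frame[i] - g$start_frame[i]) %/% 2
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, start_frame = g$start_frame[i], end_frame = mid,
        error = g$error[i], maneuver_ordinal = g$maneuver_ordinal[i],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        label = sample(alphabet, 1), start_frame = mid,
        end_frame = g$end_frame[i], error = FALSE,
        maneuver_ordinal = g$maneuver_ordinal[i], stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, start_frame = g$start_frame[i],
        end_frame = g$end_frame[i], error = g$error[i],
        maneuver_ordinal = g$maneuver_ordinal[i], stringsAsFactors = FALSE)
    }
  }
  n_dropped <- 0L
  if (length(rows)) {
    ng <- do.call(rbind, rows)
    if (boundary_jitter_frames > 0 && nrow(ng) > 1) {
      for (i in seq_len(nrow(ng) - 1)) {
        j <- as.integer(round(stats::runif(1, -boundary_jitter_frames,
                                           boundary_jitter_frames)))
        b <- ng$end_frame[i] + j
        b <- max(ng$start_frame[i], min(b, ng$end_frame[i + 1]))
        ng$end_frame[i] <- b
        ng$start_frame[i + 1] <- b
      }
    }
    keep <- ng$start_frame < ng$end_frame
    n_dropped <- sum(!keep)
    ng <- ng[keep, , drop = FALSE]
    ng$ordinal <- seq_len(nrow(ng)) - 1L
    ng <- ng[, c("ordinal", "label", "start_frame", "end_frame", "error",
                 "maneuver_ordinal")]
  } else {
    ng <- trial$gestures[0, ]
  }
  rownames(ng) <- NULL
  list(trial = surg_trial(trial$trial_id, trial$maneuvers, ng, trial$skill,
                          trial$surgeon_id),
       n_dropped = n_dropped)
}
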