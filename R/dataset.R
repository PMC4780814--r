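#' Assemble annotated trials from the three parsed tables
#'
#' Cross-references gesture, maneuver and skill records into per-trial
#' objects. Gestures reference their parent maneuver through the 1-based row
#' index of the whole maneuver table; the reference is resolved to a 0-based
#' maneuver ordinal within the trial. Violations (orphan gestures, references
#' crossing trials or out of range, trials with activity but no skill record)
#' are collected in a validation report rather than silently repaired; a
#' record is either assembled satisfying every invariant or listed there.
#' Trials present only in the skill table are retained with empty sequences
#' and flagged as a warning.
#'
#' @param gestures Data frame from [read_gesture_table()].
#' @param maneuvers Data frame from [read_maneuver_table()].
#' @param skills Data frame from [read_skill_table()].
#' @param vocabulary A [surg_vocabulary].
#' @return A `surg_dataset`: list with `trials` (named list of `surg_trial`),
#'   `vocabulary`, and `validation` (data frame with columns `trial_id`,
#'   `severity` (`error`/`warning`), `problem`).
#' @export
assemble_dataset <- function(gestures, maneuvers, skills,
                             vocabulary = default_vocabulary()) {
  problems <- list()
  note <- function(trial_id, severity, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      trial_id = trial_id, severity = severity, problem = problem,
      stringsAsFactors = FALSE)
  }

  # frame columns are optional in the deposited dialects
  for (col in c("start_frame", "end_frame")) {
    if (is.null(gestures[[col]])) {
      gestures[[col]] <- rep(NA_integer_, nrow(gestures))
    }
    if (is.null(maneuvers[[col]])) {
      maneuvers[[col]] <- rep(NA_integer_, nrow(maneuvers))
    }
  }

  trial_ids <- sort(unique(c(gestures$trial_id, maneuvers$trial_id,
                             skills$trial_id)))
  trials <- list()
  for (tid in trial_ids) {
    g <- gestures[gestures$trial_id == tid, , drop = FALSE]
    m <- maneuvers[maneuvers$trial_id == tid, , drop = FALSE]
    s <- skills[skills$trial_id == tid, , drop = FALSE]

    if (nrow(s) == 0) {
      if (nrow(g) > 0 || nrow(m) > 0) {
        note(tid, "error", "trial has activity records but no skill record")
      }
      skill <- NULL
    } else {
      items <- if (all(paste0("grs", 1:6) %in% names(s))) {
        as.integer(s[1, paste0("grs", 1:6)])
      } else NULL
      skill <- list(trial_id = tid,
                    experience_class = s$experience_class[1],
                    grs_total = s$grs_total[1],
                    grs_items = items)
      if (nrow(g) == 0 && nrow(m) == 0) {
        note(tid, "warning", "trial present only in skill table; empty sequences")
      }
    }

    # resolve global maneuver rows to within-trial ordinals
    man_ord <- rep(NA_integer_, nrow(g))
    if (nrow(g) > 0) {
      rows_all <- which(maneuvers$trial_id == tid)   # global row numbers
      for (i in seq_len(nrow(g))) {
        ref <- g$maneuver_row[i]
        if (is.na(ref) || ref < 1 || ref > nrow(maneuvers)) {
          note(tid, "error", sprintf(
            "gesture ordinal %d references maneuver row %s out of range",
            g$ordinal[i], as.character(ref)))
        } else if (maneuvers$trial_id[ref] != tid) {
          note(tid, "error", sprintf(
            "gesture ordinal %d references a maneuver in trial %d",
            g$ordinal[i], maneuvers$trial_id[ref]))
        } else {
          man_ord[i] <- match(ref, rows_all) - 1L
        }
      }
    }

    gtab <- data.frame(
      ordinal = g$ordinal,
      label = g$label,
      start_frame = g$start_frame,
      end_frame = g$end_frame,
      error = g$error,
      maneuver_ordinal = man_ord,
      stringsAsFactors = FALSE
    )
    mtab <- data.frame(
      ordinal = m$ordinal,
      label_raw = m$label_raw,
      label_collapsed = m$label_collapsed,
      start_frame = m$start_frame,
      end_frame = m$end_frame,
      incomplete = m$incomplete,
      stringsAsFactors = FALSE
    )
    if (nrow(gtab) > 0 && !all(is.na(gtab$maneuver_ordinal))) {
      mo <- gtab$maneuver_ordinal
      if (any(diff(mo[!is.na(mo)]) < 0)) {
        note(tid, "error", "gesture maneuver references are not monotone in trial order")
      }
    }
    trials[[as.character(tid)]] <- surg_trial(tid, mtab, gtab, skill)
  }

  validation <- if (length(problems)) {
    do.call(rbind, problems)
  } else {
    data.frame(trial_id = integer(), severity = character(),
               problem = character(), stringsAsFactors = FALSE)
  }
  structure(list(trials = trials, vocabulary = vocabulary,
                 validation = validation),
            class = "surg_dataset")
}

#' Construct a single annotated trial
#'
#' @param trial_id Integer trial identifier.
#' @param maneuvers Data frame with columns `ordinal`, `label_raw`,
#'   `label_collapsed`, `start_frame`, `end_frame`, `incomplete`.
#' @param gestures Data frame with columns `ordinal`, `label`, `start_frame`,
#'   `end_frame`, `error`, `maneuver_ordinal`.
#' @param skill List with `experience_class`, `grs_total`, optional
#'   `grs_items`, or `NULL`.
#' @param surgeon_id Optional surgeon identifier.
#' @return A `surg_trial`.
#' @export
surg_trial <- function(trial_id, maneuvers, gestures, skill = NULL,
                       surgeon_id = NA_character_) {
  structure(list(trial_id = as.integer(trial_id), surgeon_id = surgeon_id,
                 maneuvers = maneuvers, gestures = gestures, skill = skill),
            class = "surg_trial")
}

#' @export
print.surg_trial <- function(x, ...) {
  cat(sprintf("surg_trial %d: %d maneuvers, %d gestures\n",
              x$trial_id, nrow(x$maneuvers), nrow(x$gestures)))
  invisible(x)
}

#' @export
print.surg_dataset <- function(x, ...) {
  nerr <- sum(x$validation$severity == "error")
  cat(sprintf("surg_dataset: %d trials (%d validation errors, %d warnings)\n",
              length(x$trials), nerr, nrow(x$validation) - nerr))
  invisible(x)
}

#' Extract the trials of a dataset
#' @param dataset A `surg_dataset`.
#' @return Named list of `surg_trial`, ordered by trial id.
#' @export
trials <- function(dataset) dataset$trials

#' Maneuver label sequence of a trial
#'
#' @param trial A `surg_trial`.
#' @param collapsed Use collapsed labels (default) or raw identifiers.
#' @return Character vector of maneuver labels in temporal order.
#' @export
maneuver_sequence <- function(trial, collapsed = TRUE) {
  m <- trial$maneuvers
  if (nrow(m) == 0) return(character(0))
  if (collapsed) m$label_collapsed else m$label_raw
}

#' Gesture label sequences within one collapsed maneuver label
#'
#' Returns one ordered gesture-label sequence per instance of the requested
#' collapsed maneuver label, in temporal order; an empty list when the trial
#' has no such maneuver.
#'
#' @param trial A `surg_trial`.
#' @param maneuver_label A collapsed maneuver label, e.g. `"TLK"`.
#' @return List of character vectors.
#' @export
gesture_sequence_within <- function(trial, maneuver_label) {
  m <- trial$maneuvers
  idx <- which(m$label_collapsed == maneuver_label)
  lapply(m$ordinal[idx], function(o) {
    trial$gestures$label[!is.na(trial$gestures$maneuver_ordinal) &
                           trial$gestures$maneuver_ordinal == o]
  })
}

#' Check every type invariant of an assembled dataset
#'
#' Verifies ordering of ordinals, half-open frame spans, non-overlap of
#' maneuver spans, containment of gestures within their parent maneuver span
#' (frame checks apply only where spans are present), and GRS consistency.
#'
#' @param dataset A `surg_dataset`.
#' @return Data frame of violations (`trial_id`, `problem`); zero rows when
#'   clean.
#' @export
check_invariants <- function(dataset) {
  probs <- list()
  note <- function(tid, p) {
    probs[[length(probs) + 1L]] <<- data.frame(trial_id = tid, problem = p,
                                               stringsAsFactors = FALSE)
  }
  for (tr in dataset$trials) {
    m <- tr$maneuvers; g <- tr$gestures; tid <- tr$trial_id
    if (nrow(m) > 1 && any(diff(m$ordinal) != 1)) {
      note(tid, "maneuver ordinals not consecutive")
    }
    if (nrow(g) > 1 && any(diff(g$ordinal) != 1)) {
      note(tid, "gesture ordinals not consecutive")
    }
    has_mf <- nrow(m) > 0 && !anyNA(m$start_frame)
    has_gf <- nrow(g) > 0 && !anyNA(g$start_frame)
    if (has_mf) {
      if (any(m$start_frame >= m$end_frame)) note(tid, "empty maneuver span")
      if (nrow(m) > 1 && any(m$start_frame[-1] < m$end_frame[-nrow(m)])) {
        note(tid, "overlapping maneuver spans")
      }
    }
    if (has_gf) {
      if (any(g$start_frame >= g$end_frame)) note(tid, "empty gesture span")
      if (nrow(g) > 1 && any(diff(g$start_frame) < 0)) {
        note(tid, "gesture spans not time-ordered")
      }
      if (has_mf) {
        mo <- g$maneuver_ordinal
        ok <- !is.na(mo)
        within <- g$start_frame[ok] >= m$start_frame[mo[ok] + 1L] &
          g$end_frame[ok] <= m$end_frame[mo[ok] + 1L]
        if (!all(within)) note(tid, "gesture outside parent maneuver span")
      }
    }
    if (nrow(g) > 0) {
      mo <- g$maneuver_ordinal
      if (anyNA(mo) || any(mo < 0 | mo >= nrow(m))) {
        note(tid, "gesture references nonexistent maneuver ordinal")
      } else if (any(diff(mo) < 0)) {
        note(tid, "gestures not contiguous by maneuver")
      }
    }
    if (!is.null(tr$skill) && !is.null(tr$skill$grs_items)) {
      it <- tr$skill$grs_items
      if (length(it) != 6 || any(it < 1 | it > 5) ||
          sum(it) != tr$skill$grs_total) {
        note(tid, "GRS items inconsistent with total")
      }
    }
  }
  if (length(probs)) do.call(rbind, probs) else {
    data.frame(trial_id = integer(), problem = character(),
               stringsAsFactors = FALSE)
  }
}

#' Read a directory holding the three deposited tables
#'
#' Expects `gestures.txt`, `maneuvers.txt` and `skills.txt` (the S1/S2/S3
#' dialects) in `dir`, plus optionally `vocabulary.yaml`.
#'
#' @param dir Directory path.
#' @param vocabulary Vocabulary to use; defaults to `vocabulary.yaml` in the
#'   directory when present, else [default_vocabulary()].
#' @param strict Passed to the readers.
#' @return A `surg_dataset`.
#' @export
read_dataset_dir <- function(dir, vocabulary = NULL, strict = TRUE) {
  if (is.null(vocabulary)) {
    vp <- file.path(dir, "vocabulary.yaml")
    vocabulary <- if (file.exists(vp)) read_vocabulary(vp) else default_vocabulary()
  }
  assemble_dataset(
    read_gesture_table(file.path(dir, "gestures.txt"), vocabulary, strict),
    read_maneuver_table(file.path(dir, "maneuvers.txt"), vocabulary, strict),
    read_skill_table(file.path(dir, "skills.txt")),
    vocabulary
  )
}
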