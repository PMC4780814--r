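#' Skill classification schemes
#'
#' Trials are assigned to skill classes either from self-reported experience
#' (attending surgeons with robotic practices are experts, trainees novices)
#' or from the expert-assigned global rating score (GRS; six OSATS items, the
#' "use of assistants" item omitted, each scored 1–5, total 6–30):
#' \describe{
#'   \item{experience}{class 1 is expert, class 0 novice; never intermediate.}
#'   \item{grs1}{total below 14 is novice, above 22 expert, otherwise
#'     intermediate.}
#'   \item{grs2}{a score of 3 or more on at most two items is novice; more
#'     than 3 on at least four items with every remaining item at least 3 is
#'     expert; otherwise intermediate.}
#'   \item{grs3}{at most 3 on all items is novice; more than 3 on all items
#'     is expert; otherwise intermediate.}
#' }
#' Schemes `grs2` and `grs3` need the six per-item scores; data deposited
#' with totals only supports `experience` and `grs1`.
#'
#' @param record A skill record: list with `experience_class`, `grs_total`,
#'   optional `grs_items` (as on an assembled trial).
#' @return Classification as a character scalar: `"expert"`, `"intermediate"`
#'   or `"novice"`.
#' @export
classify_experience <- function(record) {
  if (is.null(record) || is.null(record$experience_class)) {
    stop("missing skill record")
  }
  cls <- record$experience_class
  if (!cls %in% c(0L, 1L)) stop("experience class must be 0 or 1")
  if (cls == 1L) "expert" else "novice"
}

#' @rdname classify_experience
#' @param total Integer GRS total in `[6, 30]`.
#' @export
classify_grs1 <- function(total) {
  if (is.na(total) || total < 6 || total > 30) {
    stop("GRS total must lie in [6, 30]")
  }
  if (total < 14) "novice" else if (total > 22) "expert" else "intermediate"
}

#' @rdname classify_experience
#' @param items Integer vector of the six GRS item scores, each in `[1, 5]`.
#' @export
classify_grs2 <- function(items) {
  check_items(items)
  n_ge3 <- sum(items >= 3)
  n_gt3 <- sum(items > 3)
  if (n_ge3 <= 2) return("novice")
  # "remaining items": every item not counted in the >3 set must be >= 3
  if (n_gt3 >= 4 && all(items[items <= 3] >= 3)) return("expert")
  "intermediate"
}

#' @rdname classify_experience
#' @export
classify_grs3 <- function(items) {
  check_items(items)
  if (all(items <= 3)) "novice" else if (all(items > 3)) "expert" else "intermediate"
}

check_items <- function(items) {
  if (length(items) != 6) stop("exactly six GRS item scores are required")
  if (anyNA(items) || any(items < 1 | items > 5)) {
    stop("GRS item scores must lie in [1, 5]")
  }
  invisible(items)
}

#' Classify every trial of a dataset under one scheme
#'
#' @param dataset A `surg_dataset`.
#' @param scheme One of `"experience"`, `"grs1"`, `"grs2"`, `"grs3"`.
#' @return Data frame with columns `trial_id`, `scheme`, `class`.
#' @export
skill_assignments <- function(dataset,
                              scheme = c("experience", "grs1", "grs2", "grs3")) {
  scheme <- match.arg(scheme)
  rows <- lapply(dataset$trials, function(tr) {
    sk <- tr$skill
    if (is.null(sk)) return(NULL)
    cls <- switch(scheme,
      experience = classify_experience(sk),
      grs1 = classify_grs1(sk$grs_total),
      grs2 = {
        if (is.null(sk$grs_items)) {
          stop("scheme grs2 needs per-item GRS scores; only totals available")
        }
        classify_grs2(sk$grs_items)
      },
      grs3 = {
        if (is.null(sk$grs_items)) {
          stop("scheme grs3 needs per-item GRS scores; only totals available")
        }
        classify_grs3(sk$grs_items)
      })
    data.frame(trial_id = tr$trial_id, scheme = scheme, class = cls,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else {
    data.frame(trial_id = integer(), scheme = character(), class = character(),
               stringsAsFactors = FALSE)
  }
}

#' Split trials of a dataset by skill class
#' @inheritParams skill_assignments
#' @return Named list of lists of `surg_trial` (`expert`, `novice`, and
#'   `intermediate` when non-empty).
#' @export
split_by_skill <- function(dataset, scheme = "experience") {
  asg <- skill_assignments(dataset, scheme)
  out <- lapply(split(asg$trial_id, asg$class), function(ids) {
    dataset$trials[as.character(ids)]
  })
  out[order(match(names(out), c("expert", "intermediate", "novice")))]
}
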