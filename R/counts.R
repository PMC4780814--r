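#' Segment-count metrics for one trial
#'
#' Computes the fixed descriptive panel: total and incomplete maneuvers,
#' IMS count, total and error gestures, total gestures within each of the
#' five collapsed maneuvers (`gestures_in:<M>`), and counts of each named
#' gesture within each maneuver (`gesture_count:<M>_<g>`). Combinations
#' absent from the trial are 0. By construction `total_gestures` equals the
#' sum of the five `gestures_in:` entries and `error_gestures <=
#' total_gestures`.
#'
#' @param trial A `surg_trial`.
#' @param vocabulary A [surg_vocabulary]; its collapsed maneuver labels and
#'   named gestures define the panel.
#' @param gesture_panel Gesture labels for the per-gesture counts; defaults
#'   to the nine named gestures.
#' @return Named numeric vector of counts.
#' @export
compute_trial_counts <- function(trial, vocabulary = default_vocabulary(),
                                 gesture_panel = c("DN", "GN", "RN", "PN",
                                                   "AD", "LS", "GT", "PT",
                                                   "TK")) {
  man <- vocabulary$maneuvers_collapsed
  m <- trial$maneuvers
  g <- trial$gestures
  out <- c(
    total_maneuvers = nrow(m),
    incomplete_maneuvers = sum(m$incomplete),
    ims_count = sum(m$label_collapsed == "IMS"),
    total_gestures = nrow(g),
    error_gestures = sum(g$error)
  )
  gman <- if (nrow(g)) m$label_collapsed[g$maneuver_ordinal + 1L] else character(0)
  for (M in man) {
    out[paste0("gestures_in:", M)] <- sum(gman == M, na.rm = TRUE)
  }
  for (M in man) for (gl in gesture_panel) {
    out[paste0("gesture_count:", M, "_", gl)] <-
      sum(gman == M & g$label == gl, na.rm = TRUE)
  }
  out
}

#' Count table for a whole dataset
#' @param dataset A `surg_dataset`.
#' @inheritParams compute_trial_counts
#' @return Data frame, one row per trial (`trial_id` first column) and one
#'   column per metric.
#' @export
trial_count_table <- function(dataset, gesture_panel = c("DN", "GN", "RN",
                                                         "PN", "AD", "LS",
                                                         "GT", "PT", "TK")) {
  rows <- lapply(dataset$trials, compute_trial_counts,
                 vocabulary = dataset$vocabulary,
                 gesture_panel = gesture_panel)
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab <- cbind(trial_id = vapply(dataset$trials, function(t) t$trial_id,
                                 integer(1)), tab)
  rownames(tab) <- NULL
  tab
}

#' Skill-group mean of a count metric with a percentile bootstrap interval
#'
#' Trials are the resampling unit (each trial is one data point; 1000
#' resamples and a 95% interval by default), resampled with replacement
#' within each skill group.
#'
#' @param dataset A `surg_dataset`.
#' @param metric Metric name as produced by [compute_trial_counts()].
#' @param scheme Skill scheme, see [skill_assignments()].
#' @param n_boot,seed,level Bootstrap settings.
#' @return Data frame, one row per group: `metric`, `group`, `n`, `mean`,
#'   `bi_low`, `bi_high`, `n_boot`, `seed`.
#' @export
group_mean_bi <- function(dataset, metric, scheme = "experience",
                          n_boot = 1000, seed = NULL, level = 0.95) {
  groups <- split_by_skill(dataset, scheme)
  rows <- lapply(names(groups), function(gname) {
    trs <- groups[[gname]]
    if (length(trs) == 0) stop("empty skill group: ", gname)
    vals <- vapply(trs, function(tr) {
      unname(compute_trial_counts(tr, dataset$vocabulary)[metric])
    }, numeric(1))
    gseed <- if (is.null(seed)) NULL else seed + match(gname, names(groups))
    bs <- bootstrap_statistic(vals, mean, bootstrap_spec(n_boot, gseed, level))
    data.frame(metric = metric, group = gname, n = length(vals),
               mean = bs$estimate, bi_low = bs$ci_low, bi_high = bs$ci_high,
               n_boot = n_boot,
               seed = if (is.null(gseed)) NA_integer_ else gseed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Interval-non-overlap significance rule
#'
#' Two groups differ significantly on a metric when a group's point estimate
#' falls outside the other group's 95% bootstrap interval. Under the default
#' rule `"either"` one direction suffices; under `"both"` the exclusion must
#' hold in both directions. The report states which direction(s) fired.
#'
#' @param stat_a,stat_b Single rows of the data frame returned by
#'   [group_mean_bi()] (same metric, different groups).
#' @param rule `"either"` (default) or `"both"`.
#' @return List with `significant` (logical), `rule`, and
#'   `directions` (character: which group means fell outside the other
#'   interval).
#' @export
significance_flag <- function(stat_a, stat_b, rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (!identical(stat_a$metric, stat_b$metric)) {
    stop("significance_flag compares two groups on the same metric")
  }
  a_out <- stat_a$mean < stat_b$bi_low || stat_a$mean > stat_b$bi_high
  b_out <- stat_b$mean < stat_a$bi_low || stat_b$mean > stat_a$bi_high
  dirs <- c(
    if (a_out) sprintf("mean(%s) outside BI(%s)", stat_a$group, stat_b$group),
    if (b_out) sprintf("mean(%s) outside BI(%s)", stat_b$group, stat_a$group)
  )
  list(significant = if (rule == "either") a_out || b_out else a_out && b_out,
       rule = rule, directions = if (is.null(dirs)) character(0) else dirs)
}
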