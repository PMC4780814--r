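#' Bootstrap specification
#'
#' Shared settings for the trial-level percentile bootstrap used throughout
#' the pipeline: 1000 resamples and a 95% interval by default, resampling
#' whole trials with replacement.
#'
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param level Interval level in (0, 1).
#' @return A `bootstrap_spec` list.
#' @export
bootstrap_spec <- function(n_boot = 1000, seed = NULL, level = 0.95) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  structure(list(n_boot = as.integer(n_boot), seed = seed, level = level),
            class = "bootstrap_spec")
}

#' Percentile bootstrap of an arbitrary trial-level statistic
#'
#' Computes the statistic on the original trial set, then on `n_boot`
#' resamples drawn with replacement from a canonical ordering of the trials
#' (sorted by trial id when the elements are `surg_trial`s), and returns the
#' percentile interval of the replicate values (linear interpolation between
#' order statistics). Replicates on which the statistic is undefined (`NA`)
#' are dropped and counted; when more than half are undefined the interval is
#' flagged unreliable. With a fixed seed the output is reproducible
#' bit-for-bit and invariant to the input ordering of the trials.
#'
#' @param trials List (e.g. of `surg_trial`) or atomic vector; the resampling
#'   unit is one element.
#' @param statistic Function mapping a list/vector of trials to one number
#'   (may return `NA` when undefined on a resample).
#' @param spec A [bootstrap_spec()].
#' @return List with `estimate`, `ci_low`, `ci_high`, `level`, `n`, `n_boot`,
#'   `replicates`, `n_undefined`, `unreliable`, `degenerate` (single usable
#'   replicate), `seed`.
#' @export
bootstrap_statistic <- function(trials, statistic, spec = bootstrap_spec()) {
  n <- length(trials)
  if (n == 0) stop("empty trial set")
  trials <- canonical_order(trials)
  estimate <- statistic(trials)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  reps <- vapply(seq_len(spec$n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    as.numeric(statistic(trials[idx]))
  }, numeric(1))
  usable <- reps[!is.na(reps)]
  n_undef <- spec$n_boot - length(usable)
  alpha <- (1 - spec$level) / 2
  if (length(usable) == 0) {
    ci <- c(NA_real_, NA_real_)
  } else {
    ci <- unname(stats::quantile(usable, c(alpha, 1 - alpha), type = 7))
  }
  list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
       level = spec$level, n = n, n_boot = spec$n_boot,
       replicates = reps, n_undefined = n_undef,
       unreliable = n_undef > spec$n_boot / 2,
       degenerate = length(usable) <= 1,
       seed = spec$seed)
}

# sort surg_trial lists by trial_id so resampling indexes a canonical order
canonical_order <- function(trials) {
  if (is.list(trials) && length(trials) &&
      all(vapply(trials, inherits, logical(1), "surg_trial"))) {
    ids <- vapply(trials, function(t) t$trial_id, integer(1))
    trials <- trials[order(ids)]
  }
  trials
}
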