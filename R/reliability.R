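#' Levenshtein edit distance between label sequences
#'
#' Minimal number of unit-cost deletions, insertions and substitutions
#' converting one sequence into the other, by the standard two-row dynamic
#' program. Works on arbitrary label alphabets; a character scalar is split
#' into single characters, so `levenshtein("robots", "robust")` is 3.
#'
#' @param a,b Character vectors of labels (or single strings).
#' @return Non-negative integer distance.
#' @export
levenshtein <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1L,          # deletion
                        cur[j] + 1L,               # insertion
                        prev[j] + (a[i] != b[j]))  # substitution
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

as_labels <- function(x) {
  if (is.character(x) && length(x) == 1 && !is.na(x) && nchar(x) != 1) {
    x <- strsplit(x, "")[[1]]
  }
  as.character(x)
}

#' Edit distance normalised per 10 labels of a reference sequence
#'
#' @param a,b Label sequences.
#' @param reference Which sequence supplies the denominator: `"b"` (default;
#'   conventionally the verified annotation) or `"a"`.
#' @return `levenshtein(a, b) * 10 / length(reference)`.
#' @export
normalized_ld_per10 <- function(a, b, reference = c("b", "a")) {
  reference <- match.arg(reference)
  ref <- if (reference == "b") as_labels(b) else as_labels(a)
  if (length(ref) == 0) stop("reference sequence is empty")
  levenshtein(a, b) * 10 / length(ref)
}

#' Mean normalised edit distance across trials with a bootstrap interval
#'
#' Per-trial normalised distances (per 10 reference labels) are averaged
#' unweighted across trials; the 95% interval is a trial-level percentile
#' bootstrap. With a single trial the interval is flagged unavailable.
#'
#' @param seqs_a,seqs_b Lists of label sequences, paired by position (one
#'   pair per trial).
#' @param reference `"b"` or `"a"`, as in [normalized_ld_per10()].
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param level Interval level.
#' @return List with `per_trial` (data frame: `trial`, `raw_ld`, `ref_len`,
#'   `nld_per10`), `mean_nld`, `ci_low`, `ci_high`, `ci_available`,
#'   `reference`.
#' @export
mean_ld_with_ci <- function(seqs_a, seqs_b, reference = c("b", "a"),
                            n_boot = 1000, seed = NULL, level = 0.95) {
  reference <- match.arg(reference)
  stopifnot(length(seqs_a) == length(seqs_b), length(seqs_a) >= 1)
  per <- data.frame(
    trial = seq_along(seqs_a),
    raw_ld = mapply(levenshtein, seqs_a, seqs_b),
    ref_len = vapply(if (reference == "b") seqs_b else seqs_a,
                     function(s) length(as_labels(s)), integer(1))
  )
  per$nld_per10 <- per$raw_ld * 10 / per$ref_len
  if (nrow(per) < 2) {
    return(list(per_trial = per, mean_nld = mean(per$nld_per10),
                ci_low = NA_real_, ci_high = NA_real_, ci_available = FALSE,
                reference = reference))
  }
  bs <- bootstrap_statistic(per$nld_per10, mean,
                            bootstrap_spec(n_boot, seed, level))
  list(per_trial = per, mean_nld = bs$estimate,
       ci_low = bs$ci_low, ci_high = bs$ci_high, ci_available = TRUE,
       reference = reference)
}

#' Frame-level Cohen's kappa between two annotation tracks
#'
#' Chance-corrected per-frame agreement \eqn{(p_o - p_e)/(1 - p_e)} from the
#' confusion table over the category's labels plus the background label.
#' Because one frame may carry labels from several arm categories, kappa is
#' computed separately per category track. When both tracks are a single
#' constant shared label (`p_e = 1`), kappa is defined as 1 for identical
#' tracks and flagged undefined otherwise.
#'
#' @param track1,track2 `surg_frame_track`s (or plain character vectors) of
#'   equal length.
#' @return List with `kappa`, `p_o`, `p_e`, `n_frames`, `undefined`.
#' @export
frame_kappa <- function(track1, track2) {
  l1 <- if (inherits(track1, "surg_frame_track")) track1$labels else as.character(track1)
  l2 <- if (inherits(track2, "surg_frame_track")) track2$labels else as.character(track2)
  if (inherits(track1, "surg_frame_track") && inherits(track2, "surg_frame_track") &&
      !identical(track1$category, track2$category)) {
    stop("tracks belong to different categories")
  }
  if (length(l1) != length(l2)) stop("tracks differ in length")
  n <- length(l1)
  if (n == 0) stop("empty tracks")
  labs <- sort(unique(c(l1, l2)))
  f1 <- factor(l1, levels = labs); f2 <- factor(l2, levels = labs)
  tab <- table(f1, f2) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (isTRUE(all.equal(p_e, 1))) {
    identical_tracks <- all(l1 == l2)
    return(list(kappa = if (identical_tracks) 1 else NA_real_,
                p_o = p_o, p_e = p_e, n_frames = n,
                undefined = !identical_tracks))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e,
       n_frames = n, undefined = FALSE)
}

#' Per-category kappa pooled over trials
#'
#' Concatenates frames across trials within each category (pooled kappa) and
#' also reports per-trial kappas.
#'
#' @param tracks_a,tracks_b Lists of `surg_frame_track`s paired by position;
#'   each element carries its category.
#' @return List with `pooled` (data frame: `category`, `kappa`, `n_frames`)
#'   and `per_trial` (data frame: `trial`, `category`, `kappa`).
#' @export
kappa_by_category <- function(tracks_a, tracks_b) {
  stopifnot(length(tracks_a) == length(tracks_b))
  cats <- vapply(tracks_a, function(t) t$category, character(1))
  per <- data.frame(
    trial = seq_along(tracks_a), category = cats,
    kappa = mapply(function(a, b) frame_kappa(a, b)$kappa, tracks_a, tracks_b),
    stringsAsFactors = FALSE
  )
  pooled <- do.call(rbind, lapply(split(seq_along(tracks_a), cats), function(i) {
    la <- unlist(lapply(tracks_a[i], function(t) t$labels))
    lb <- unlist(lapply(tracks_b[i], function(t) t$labels))
    k <- frame_kappa(la, lb)
    data.frame(category = cats[i[1]], kappa = k$kappa, n_frames = k$n_frames,
               stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  list(pooled = pooled, per_trial = per)
}
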