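# Independent exhaustive-recursion edit-distance oracle for short sequences;
# kept free of the package's dynamic program on purpose.
lev_oracle <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(lev_oracle(a[-1], b) + 1,
      lev_oracle(a, b[-1]) + 1,
      lev_oracle(a[-1], b[-1]) + (a[1] != b[1]))
}

# direct-summation conditional entropy oracle
centropy_oracle <- function(P, m, base = 2) {
  h <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) h <- h - m[i] * P[i, j] * log(P[i, j], base = base)
  }
  h
}

# toy trial: maneuvers by raw label (with incomplete flags), gestures as a
# list of label vectors, one per maneuver; frames tiled 10 per gesture
make_toy_trial <- function(trial_id, man_raw, gestures,
                           incomplete = rep(FALSE, length(man_raw)),
                           errors = NULL, experience_class = 0L,
                           grs_items = NULL) {
  vocab <- default_vocabulary()
  stopifnot(length(man_raw) == length(gestures))
  g_labels <- unlist(gestures)
  g_man <- rep(seq_along(gestures) - 1L, lengths(gestures))
  if (is.null(errors)) errors <- rep(FALSE, length(g_labels))
  g_end <- cumsum(rep(10L, length(g_labels)))
  g_start <- g_end - 10L
  m_end <- cumsum(vapply(seq_along(gestures), function(i) {
    10L * length(gestures[[i]])
  }, integer(1)))
  m_start <- c(0L, m_end[-length(m_end)])
  mans <- data.frame(ordinal = seq_along(man_raw) - 1L, label_raw = man_raw,
                     label_collapsed = unname(vocab$collapse_map[man_raw]),
                     start_frame = m_start, end_frame = m_end,
                     incomplete = incomplete, stringsAsFactors = FALSE)
  gest <- data.frame(ordinal = seq_along(g_labels) - 1L, label = g_labels,
                     start_frame = g_start, end_frame = g_end,
                     error = errors, maneuver_ordinal = g_man,
                     stringsAsFactors = FALSE)
  skill <- list(trial_id = trial_id, experience_class = experience_class,
                grs_total = if (is.null(grs_items)) 12L else sum(grs_items),
                grs_items = grs_items)
  surg_trial(trial_id, mans, gest, skill)
}

# minimal trial whose maneuver sequence is exactly `labels` (no gestures)
vocabless_trial <- function(trial_id, labels) {
  n <- length(labels)
  surg_trial(
    trial_id,
    data.frame(ordinal = seq_len(n) - 1L, label_raw = labels,
               label_collapsed = labels, start_frame = NA_integer_,
               end_frame = NA_integer_, incomplete = FALSE,
               stringsAsFactors = FALSE),
    data.frame(ordinal = integer(0), label = character(0),
               start_frame = integer(0), end_frame = integer(0),
               error = logical(0), maneuver_ordinal = integer(0),
               stringsAsFactors = FALSE)
  )
}

# write the three toy tables and return their paths
write_toy_tables <- function(dir, gestures, maneuvers, skills) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "gestures.txt")
  mp <- file.path(dir, "maneuvers.txt")
  sp <- file.path(dir, "skills.txt")
  writeLines(gestures, gp)
  writeLines(maneuvers, mp)
  writeLines(skills, sp)
  list(gestures = gp, maneuvers = mp, skills = sp)
}
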