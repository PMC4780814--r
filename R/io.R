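#' Read the deposited annotation tables
#'
#' The three dialects are header-optional, tab- (or whitespace-) delimited
#' text, one record per row, rows in temporal order within each trial:
#' \describe{
#'   \item{gesture table}{trial number; gesture identifier; error flag
#'     (no error = 0, error = 1); row index (1-based, over the whole maneuver
#'     table) of the parent maneuver.}
#'   \item{maneuver table}{trial number; raw maneuver identifier; incomplete
#'     flag (complete = 0, incomplete = 1).}
#'   \item{skill table}{trial number; experience-based skill class
#'     (novice = 0, expert = 1); total global rating score. Six further
#'     columns with per-item GRS scores are accepted when present.}
#' }
#' Row order within a trial defines temporal order; the dialects carry no
#' frame times.
#'
#' @param path File path.
#' @param vocabulary A [surg_vocabulary] used to validate identifiers.
#' @param strict If `TRUE` (default) unknown labels are an error; otherwise
#'   they are auto-registered and kept.
#' @return `read_gesture_table`: data frame with columns `trial_id`, `ordinal`
#'   (0-based within trial), `label`, `error` (logical), `maneuver_row`
#'   (1-based row in the maneuver table). `read_maneuver_table`: data frame
#'   with `trial_id`, `ordinal`, `label_raw`, `label_collapsed`, `incomplete`.
#'   `read_skill_table`: data frame with `trial_id`, `experience_class`,
#'   `grs_total` and, when present, `grs1`..`grs6`.
#' @export
read_gesture_table <- function(path, vocabulary = default_vocabulary(),
                               strict = TRUE) {
  tab <- read_seg_table(path, 4, c("trial_id", "label", "error", "maneuver_row"))
  if (nrow(tab) == 0) return(tab_empty_gestures())
  tab$trial_id <- parse_int(tab$trial_id, "trial number")
  tab$maneuver_row <- parse_int(tab$maneuver_row, "maneuver row reference")
  err <- parse_int(tab$error, "error flag")
  if (!all(err %in% c(0L, 1L))) stop("error flag must be 0 or 1")
  if (strict) {
    unknown <- setdiff(tab$label, vocabulary$gestures$label)
    if (length(unknown)) {
      stop("unknown gesture identifier(s): ", paste(unknown, collapse = ", "))
    }
  }
  out <- data.frame(
    trial_id = tab$trial_id,
    ordinal = ordinal_within(tab$trial_id),
    label = tab$label,
    error = err == 1L,
    maneuver_row = tab$maneuver_row,
    stringsAsFactors = FALSE
  )
  out
}

#' @rdname read_gesture_table
#' @export
read_maneuver_table <- function(path, vocabulary = default_vocabulary(),
                                strict = TRUE) {
  tab <- read_seg_table(path, 3, c("trial_id", "label_raw", "incomplete"))
  if (nrow(tab) == 0) return(tab_empty_maneuvers())
  tab$trial_id <- parse_int(tab$trial_id, "trial number")
  inc <- parse_int(tab$incomplete, "incomplete flag")
  if (!all(inc %in% c(0L, 1L))) stop("incomplete flag must be 0 or 1")
  cm <- vocabulary$collapse_map
  unknown <- setdiff(tab$label_raw, names(cm))
  if (length(unknown)) {
    if (strict) {
      stop("unknown maneuver identifier(s): ", paste(unknown, collapse = ", "))
    }
    cm <- c(cm, stats::setNames(unknown, unknown))  # auto-register as own label
  }
  data.frame(
    trial_id = tab$trial_id,
    ordinal = ordinal_within(tab$trial_id),
    label_raw = tab$label_raw,
    label_collapsed = unname(cm[tab$label_raw]),
    incomplete = inc == 1L,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_gesture_table
#' @export
read_skill_table <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  raw <- drop_header(raw)
  if (length(raw) == 0) {
    return(data.frame(trial_id = integer(), experience_class = integer(),
                      grs_total = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(raw), "[ \t]+")
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1 || !(ncol %in% c(3L, 9L))) {
    stop("skill table rows must have 3 columns (or 9 with item scores)")
  }
  m <- do.call(rbind, parts)
  out <- data.frame(
    trial_id = parse_int(m[, 1], "trial number"),
    experience_class = parse_int(m[, 2], "experience class"),
    grs_total = parse_int(m[, 3], "GRS total"),
    stringsAsFactors = FALSE
  )
  if (!all(out$experience_class %in% c(0L, 1L))) {
    stop("experience class must be 0 (novice) or 1 (expert)")
  }
  if (anyDuplicated(out$trial_id)) {
    stop("duplicated trial id(s) in skill table: ",
         paste(unique(out$trial_id[duplicated(out$trial_id)]), collapse = ", "))
  }
  if (ncol == 9L) {
    items <- apply(m[, 4:9, drop = FALSE], 2, parse_int, what = "GRS item")
    items <- matrix(items, ncol = 6)
    colnames(items) <- paste0("grs", 1:6)
    if (any(items < 1 | items > 5)) stop("GRS item scores must lie in [1, 5]")
    bad <- rowSums(items) != out$grs_total
    if (any(bad)) {
      stop("GRS total does not equal the sum of item scores for trial(s): ",
           paste(out$trial_id[bad], collapse = ", "))
    }
    out <- cbind(out, as.data.frame(items))
  }
  out
}

#' Write annotation tables in the deposited dialects
#'
#' Inverse of the `read_*_table` readers: tab-delimited, no header, integer
#' flags. Writing then reading reproduces the records field for field.
#'
#' @param gestures,maneuvers,skills Data frames as returned by the readers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gesture_table <- function(gestures, path) {
  write_rows(path, gestures$trial_id, gestures$label,
             as.integer(gestures$error), gestures$maneuver_row)
}

#' @rdname write_gesture_table
#' @export
write_maneuver_table <- function(maneuvers, path) {
  write_rows(path, maneuvers$trial_id, maneuvers$label_raw,
             as.integer(maneuvers$incomplete))
}

#' @rdname write_gesture_table
#' @export
write_skill_table <- function(skills, path) {
  if (all(paste0("grs", 1:6) %in% names(skills))) {
    do.call(write_rows, c(list(path, skills$trial_id, skills$experience_class,
                               skills$grs_total),
                          lapply(paste0("grs", 1:6), function(k) skills[[k]])))
  } else {
    write_rows(path, skills$trial_id, skills$experience_class, skills$grs_total)
  }
}

#' Read or write a frame-level annotation track
#'
#' Tracks record one gesture label per video frame (30 fps) for one annotator
#' and one arm category. Two plain-text layouts are accepted: two columns
#' (frame index, label), or run-length triples (label, start, end) with
#' half-open `[start, end)` spans. Frames not covered receive the background
#' label.
#'
#' @param path File path.
#' @param annotator_id Identifier stored on the track.
#' @param category Arm category of the track (`left`, `right`, `both`,
#'   `camera` or `either`).
#' @param n_frames Total frame count; required for run-length input, inferred
#'   as `max(frame) + 1` for per-frame input when omitted.
#' @param background Reserved label for unannotated frames.
#' @return A `surg_frame_track`: list with `annotator_id`, `category`,
#'   `labels` (character, one per frame) and `background`.
#' @export
read_frame_track <- function(path, annotator_id = NA_character_,
                             category = "either", n_frames = NULL,
                             background = ".bg") {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  # a header line is one with no integer field at all (data rows always carry
  # a frame index or a span bound)
  if (length(raw) > 0 &&
      !any(grepl("^-?[0-9]+$", strsplit(trimws(raw[1]), "[ \t]+")[[1]]))) {
    raw <- raw[-1]
  }
  parts <- strsplit(trimws(raw), "[ \t]+")
  ncol <- unique(lengths(parts))
  if (length(raw) == 0) {
    return(frame_track(character(0), annotator_id, category, background))
  }
  if (length(ncol) != 1 || !(ncol %in% c(2L, 3L))) {
    stop("frame track rows must have 2 (frame, label) or 3 (label, start, end) columns")
  }
  m <- do.call(rbind, parts)
  if (ncol == 2L) {
    idx <- parse_int(m[, 1], "frame index")
    nf <- if (is.null(n_frames)) max(idx) + 1L else n_frames
    labels <- rep(background, nf)
    labels[idx + 1L] <- m[, 2]
  } else {
    if (is.null(n_frames)) stop("n_frames is required for run-length input")
    st <- parse_int(m[, 2], "start frame")
    en <- parse_int(m[, 3], "end frame")
    if (any(st >= en)) stop("run-length spans must satisfy start < end")
    labels <- rep(background, n_frames)
    for (i in seq_len(nrow(m))) labels[(st[i] + 1L):en[i]] <- m[i, 1]
  }
  frame_track(labels, annotator_id, category, background)
}

#' @rdname read_frame_track
#' @param track A `surg_frame_track`.
#' @param format `"frames"` for per-frame rows, `"rle"` for run-length triples.
#' @export
write_frame_track <- function(track, path, format = c("frames", "rle")) {
  format <- match.arg(format)
  if (format == "frames") {
    keep <- track$labels != track$background
    write_rows(path, which(keep) - 1L, track$labels[keep])
  } else {
    r <- rle(track$labels)
    en <- cumsum(r$lengths)
    st <- en - r$lengths
    keep <- r$values != track$background
    write_rows(path, r$values[keep], st[keep], en[keep])
  }
}

#' Construct a frame track from labels
#' @param labels Character vector, one label per frame.
#' @inheritParams read_frame_track
#' @return A `surg_frame_track`.
#' @export
frame_track <- function(labels, annotator_id = NA_character_,
                        category = "either", background = ".bg") {
  structure(list(annotator_id = annotator_id, category = category,
                 labels = as.character(labels), background = background),
            class = "surg_frame_track")
}

#' Project a trial's gestures onto a per-frame track for one arm category
#'
#' Frames covered by a gesture whose label belongs to the requested category
#' receive that gesture's label; all other frames get the background label.
#' Requires frame spans (generator output or frame-annotated data).
#'
#' @param trial A `surg_trial`.
#' @param vocabulary A [surg_vocabulary].
#' @inheritParams read_frame_track
#' @return A `surg_frame_track`.
#' @export
gestures_to_frame_track <- function(trial, vocabulary, category,
                                    annotator_id = NA_character_,
                                    background = ".bg") {
  g <- trial$gestures
  if (nrow(g) > 0 && anyNA(g$start_frame)) {
    stop("trial has no frame spans; frame tracks need frame-annotated data")
  }
  nf <- if (nrow(g) == 0) 0L else max(g$end_frame)
  labels <- rep(background, nf)
  keep <- g$label %in% category_labels(vocabulary, category)
  for (i in which(keep)) {
    labels[(g$start_frame[i] + 1L):g$end_frame[i]] <- g$label[i]
  }
  frame_track(labels, annotator_id, category, background)
}

# ---- internal helpers -------------------------------------------------------

read_seg_table <- function(path, ncol, names) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  raw <- drop_header(raw)
  if (length(raw) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), ncol), names),
                         stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(trimws(raw), "[ \t]+")
  if (any(lengths(parts) != ncol)) {
    stop("expected ", ncol, " columns in ", path)
  }
  m <- do.call(rbind, parts)
  stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), names)
}

# a header line is one whose first field is not an integer
drop_header <- function(lines) {
  if (length(lines) == 0) return(lines)
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]][1]
  if (is.na(suppressWarnings(as.integer(first))) &&
      !grepl("^-?[0-9]+$", first)) {
    lines <- lines[-1]
  }
  lines
}

parse_int <- function(x, what) {
  if (!all(grepl("^-?[0-9]+$", x))) stop("non-integer ", what)
  as.integer(x)
}

ordinal_within <- function(trial_id) {
  as.integer(stats::ave(seq_along(trial_id), trial_id,
                        FUN = function(i) seq_along(i) - 1L))
}

write_rows <- function(path, ...) {
  cols <- list(...)
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

tab_empty_gestures <- function() {
  data.frame(trial_id = integer(), ordinal = integer(), label = character(),
             error = logical(), maneuver_row = integer(),
             stringsAsFactors = FALSE)
}

tab_empty_maneuvers <- function() {
  data.frame(trial_id = integer(), ordinal = integer(), label_raw = character(),
             label_collapsed = character(), incomplete = logical(),
             stringsAsFactors = FALSE)
}
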