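#' Activity-segment vocabulary
#'
#' A vocabulary describes the hierarchical labelling scheme used to annotate a
#' surgical task: seven raw maneuver identifiers that collapse onto five
#' analysis labels (`ST`, `GPR`, `TLK`, `OLK`, `IMS`; the two-loop and one-loop
#' knots each have a left- and right-arm raw variant), and a set of gesture
#' identifiers, each tagged with the robot-arm category it belongs to
#' (`left`, `right`, `either`, `both` or `camera`).
#'
#' @param maneuvers_raw Character vector of raw maneuver identifiers.
#' @param collapse_map Named character vector mapping every raw identifier to
#'   its collapsed label. Must be total over `maneuvers_raw`.
#' @param gestures Data frame with columns `label` (unique identifiers) and
#'   `arm` (one of `left`, `right`, `either`, `both`, `camera`).
#' @return An object of class `surg_vocabulary`.
#' @export
surg_vocabulary <- function(maneuvers_raw, collapse_map, gestures) {
  stopifnot(is.character(maneuvers_raw), is.character(collapse_map),
            is.data.frame(gestures))
  if (!all(maneuvers_raw %in% names(collapse_map))) {
    stop("collapse_map must be total over the raw maneuver labels")
  }
  if (anyDuplicated(gestures$label)) {
    stop("gesture identifiers must be unique")
  }
  bad <- setdiff(gestures$arm, c("left", "right", "either", "both", "camera"))
  if (length(bad)) stop("unknown arm category: ", paste(bad, collapse = ", "))
  structure(
    list(
      maneuvers_raw = maneuvers_raw,
      maneuvers_collapsed = unique(unname(collapse_map[maneuvers_raw])),
      collapse_map = collapse_map[maneuvers_raw],
      gestures = data.frame(label = as.character(gestures$label),
                            arm = as.character(gestures$arm),
                            stringsAsFactors = FALSE)
    ),
    class = "surg_vocabulary"
  )
}

#' Default vocabulary for the suturing and knot-tying task
#'
#' Seven raw maneuvers (suture throw `ST`, grasp-pull-run `GPR`, two-loop knot
#' `TLK_L`/`TLK_R`, one-loop knot `OLK_L`/`OLK_R`, inter-maneuver segment
#' `IMS`) collapsing onto five labels, plus a 30-gesture vocabulary. Nine
#' gestures are named (`DN` drive needle, `GN` grasp needle, `RN` rotate
#' needle out of tissue, `PN` pull needle, `AD` adjustment, `LS` loop suture
#' around needle driver, `GT` grasp suture tail through loop, `PT` pull suture
#' tail through loop, `TK` tighten knot); the remainder are anonymous
#' placeholders (`G10`..`G28`) plus two camera-movement labels, so analyses
#' never depend on the identity of the unnamed labels.
#'
#' @return A `surg_vocabulary`.
#' @export
default_vocabulary <- function() {
  collapse <- c(ST = "ST", GPR = "GPR", TLK_L = "TLK", TLK_R = "TLK",
                OLK_L = "OLK", OLK_R = "OLK", IMS = "IMS")
  named <- data.frame(
    label = c("DN", "GN", "RN", "PN", "AD", "LS", "GT", "PT", "TK"),
    arm   = c("right", "either", "right", "either", "either",
              "both", "left", "left", "both"),
    stringsAsFactors = FALSE
  )
  extra <- data.frame(
    label = c(sprintf("G%02d", 10:28), "CM1", "CM2"),
    arm   = c(rep("either", 19), "camera", "camera"),
    stringsAsFactors = FALSE
  )
  surg_vocabulary(names(collapse), collapse, rbind(named, extra))
}

#' @export
print.surg_vocabulary <- function(x, ...) {
  cat("surg_vocabulary:", length(x$maneuvers_raw), "raw maneuvers ->",
      length(x$maneuvers_collapsed), "collapsed;",
      nrow(x$gestures), "gestures\n")
  invisible(x)
}

#' Read or write a vocabulary configuration file
#'
#' Vocabularies are stored as YAML with keys `collapse_map` (raw -> collapsed)
#' and `gestures` (label -> arm category).
#'
#' @param path File path.
#' @return `read_vocabulary` returns a `surg_vocabulary`; `write_vocabulary`
#'   returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  cfg <- yaml::read_yaml(path)
  cm <- unlist(cfg$collapse_map)
  ga <- unlist(cfg$gestures)
  surg_vocabulary(names(cm), cm,
                  data.frame(label = names(ga), arm = unname(ga),
                             stringsAsFactors = FALSE))
}

#' @rdname read_vocabulary
#' @param vocabulary A `surg_vocabulary`.
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "surg_vocabulary"))
  yaml::write_yaml(
    list(collapse_map = as.list(vocabulary$collapse_map),
         gestures = stats::setNames(as.list(vocabulary$gestures$arm),
                                    vocabulary$gestures$label)),
    path)
  invisible(path)
}

#' Gesture labels belonging to one arm category
#' @param vocabulary A `surg_vocabulary`.
#' @param category One of `left`, `right`, `either`, `both`, `camera`.
#' @return Character vector of labels.
#' @export
category_labels <- function(vocabulary, category) {
  vocabulary$gestures$label[vocabulary$gestures$arm == category]
}

# 31-adic rolling hash over the vocabulary's content; stamps vocabulary
# identity into run manifests (not cryptographic)
vocabulary_hash <- function(vocabulary) {
  s <- paste(c(vocabulary$collapse_map, names(vocabulary$collapse_map),
               vocabulary$gestures$label, vocabulary$gestures$arm),
             collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
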