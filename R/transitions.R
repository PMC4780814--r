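#' First-order transition model over label sequences
#'
#' Counts adjacent label pairs within each sequence (never across sequence
#' boundaries) and row-normalises to transition probabilities. Sequences are
#' per-trial at the maneuver level or per-maneuver-instance at the gesture
#' level. Consecutive identical labels count as self-transitions (they are
#' never merged). Virtual `START`/`END` states, when requested, add a
#' transition from `START` into each sequence's first label and from its last
#' label into `END`.
#'
#' @param sequences List of character vectors.
#' @param states State set (ordered label vector). Defaults to the labels
#'   observed. A label outside the state set is an error.
#' @param include_virtual Add virtual `START`/`END` states.
#' @param alpha Additive smoothing pseudo-count applied to rows with at least
#'   one outgoing transition (default 0, i.e. none).
#' @return A `transition_model`: list with `states`, `counts` (integer
#'   matrix), `probs` (row-stochastic where defined), `source_marginal`
#'   (empirical distribution of transition sources), `zero_rows` (states with
#'   no outgoing transitions), `n_transitions`, `include_virtual`.
#' @export
build_transition_model <- function(sequences, states = NULL,
                                   include_virtual = FALSE, alpha = 0) {
  sequences <- lapply(sequences, as.character)
  obs <- unique(unlist(sequences))
  if (is.null(states)) {
    states <- sort(obs)
  } else {
    bad <- setdiff(obs, states)
    if (length(bad)) stop("label(s) outside state set: ",
                          paste(bad, collapse = ", "))
  }
  if (include_virtual) states <- c("START", setdiff(states, c("START", "END")), "END")
  k <- length(states)
  counts <- matrix(0L, k, k, dimnames = list(states, states))
  for (s in sequences) {
    if (include_virtual && length(s) > 0) s <- c("START", s, "END")
    if (length(s) >= 2) {
      for (i in seq_len(length(s) - 1)) {
        counts[s[i], s[i + 1]] <- counts[s[i], s[i + 1]] + 1L
      }
    }
  }
  rs <- rowSums(counts)
  probs <- matrix(0, k, k, dimnames = dimnames(counts))
  nz <- rs > 0
  if (any(nz)) {
    num <- counts[nz, , drop = FALSE] + alpha
    probs[nz, ] <- num / rowSums(num)
  }
  total <- sum(counts)
  structure(list(
    states = states, counts = counts, probs = probs,
    source_marginal = if (total > 0) rs / total else rs,
    zero_rows = states[!nz], n_transitions = total,
    include_virtual = include_virtual
  ), class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition_model: %d states, %d transitions\n",
              length(x$states), x$n_transitions))
  invisible(x)
}

#' Hellinger distance between two discrete distributions
#'
#' Under the `normalized` convention (default)
#' \eqn{H(p,q) = \frac{1}{\sqrt 2}\sqrt{\sum_i(\sqrt{p_i}-\sqrt{q_i})^2}}
#' with range \[0, 1\]; the `unnormalized` convention omits the
#' \eqn{1/\sqrt 2} factor and has range \[0, \eqn{\sqrt 2}\].
#'
#' @param p,q Non-negative vectors of equal length, each summing to 1.
#' @param convention `"normalized"` or `"unnormalized"`.
#' @return Distance, or `NA` when either argument is an all-zero row
#'   (undefined distribution).
#' @export
hellinger <- function(p, q, convention = c("normalized", "unnormalized")) {
  convention <- match.arg(convention)
  if (length(p) != length(q)) stop("distributions differ in dimension")
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  if (sum(p) == 0 || sum(q) == 0) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("distributions must each sum to 1")
  }
  d <- sqrt(sum((sqrt(p) - sqrt(q))^2))
  if (convention == "normalized") d / sqrt(2) else d
}

#' Conditional entropy of a transition model
#'
#' \eqn{H(Y|X) = -\sum_x m(x) \sum_y P(y|x)\log P(y|x)} with \eqn{m} the
#' empirical source marginal and \eqn{0\log 0 := 0}. Zero when every row is
#' one-hot (fully predictable flow); maximal at \eqn{\log|S|} for uniform
#' rows under a uniform marginal. Virtual `START`/`END` states are excluded
#' unless requested: `START` is dropped as a source and `END` both as a
#' source and as a destination, with the remaining rows renormalised.
#'
#' @param model A `transition_model` with at least one transition.
#' @param log_base Logarithm base; 2 (bits, default) or `exp(1)` (nats).
#' @param drop_virtual Exclude virtual endpoint states (default `TRUE`).
#' @return Entropy (non-negative scalar).
#' @export
conditional_entropy <- function(model, log_base = 2, drop_virtual = TRUE) {
  if (model$n_transitions == 0) stop("model has no transitions")
  P <- model$probs
  m <- model$source_marginal
  if (drop_virtual && model$include_virtual) {
    keep <- setdiff(model$states, c("START", "END"))
    P <- P[keep, keep, drop = FALSE]
    rs <- rowSums(P)
    nz <- rs > 0
    P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
    cnt <- rowSums(model$counts[keep, keep, drop = FALSE])
    m <- if (sum(cnt) > 0) cnt / sum(cnt) else cnt
  }
  row_h <- apply(P, 1, function(r) {
    r <- r[r > 0]
    if (length(r) == 0) 0 else -sum(r * log(r, base = log_base))
  })
  sum(m * row_h)
}

#' Extract label sequences from trials at a given analysis level
#'
#' @param trials List of `surg_trial`.
#' @param level `"maneuver"` (one collapsed-label sequence per trial) or
#'   `"gesture:<M>"` (one gesture sequence per instance of maneuver `M`).
#' @return List of character vectors; empty sequences are dropped.
#' @export
extract_sequences <- function(trials, level) {
  if (identical(level, "maneuver")) {
    seqs <- lapply(trials, maneuver_sequence)
  } else if (grepl("^gesture:", level)) {
    M <- sub("^gesture:", "", level)
    seqs <- unlist(lapply(trials, gesture_sequence_within, maneuver_label = M),
                   recursive = FALSE)
  } else {
    stop("level must be \"maneuver\" or \"gesture:<maneuver>\"")
  }
  seqs[lengths(seqs) > 0]
}

#' Compare task flow between two skill groups by Hellinger distance
#'
#' For each state, the Hellinger distance between the two groups'
#' outgoing-transition probability rows, with a 95% interval from a
#' trial-level percentile bootstrap that resamples trials with replacement
#' within each group and rebuilds both transition models per replicate
#' (1000 replicates by default). States with no outgoing transitions in one
#' of the groups (or on a replicate) are flagged undefined there and dropped
#' from that replicate.
#'
#' @param trials_a,trials_b Lists of `surg_trial` (the two skill groups).
#' @param level `"maneuver"` or `"gesture:<M>"` (e.g. `"gesture:TLK"`).
#' @param states State set; default is the union observed in the two groups.
#' @param n_boot,seed,level_ci Bootstrap settings.
#' @param convention Hellinger convention, see [hellinger()].
#' @param include_virtual Include virtual `START`/`END` rows.
#' @return Data frame, one row per state: `state`, `hellinger`, `bi_low`,
#'   `bi_high`, `n_undefined` (replicates dropped for that state),
#'   `convention`.
#' @export
compare_flows <- function(trials_a, trials_b, level = "maneuver",
                          states = NULL, n_boot = 1000, seed = NULL,
                          level_ci = 0.95,
                          convention = c("normalized", "unnormalized"),
                          include_virtual = FALSE) {
  convention <- match.arg(convention)
  if (length(trials_a) == 0 || length(trials_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (is.null(states)) {
    states <- sort(unique(unlist(c(extract_sequences(trials_a, level),
                                   extract_sequences(trials_b, level)))))
  }
  per_state <- function(ta, tb) {
    ma <- build_transition_model(extract_sequences(ta, level), states,
                                 include_virtual)
    mb <- build_transition_model(extract_sequences(tb, level), states,
                                 include_virtual)
    vapply(states, function(s) {
      hellinger(ma$probs[s, ], mb$probs[s, ], convention)
    }, numeric(1))
  }
  point <- per_state(canonical_order(trials_a), canonical_order(trials_b))
  ta <- canonical_order(trials_a); tb <- canonical_order(trials_b)
  na <- length(ta); nb <- length(tb)
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(states),
                 dimnames = list(NULL, states))
  for (b in seq_len(n_boot)) {
    reps[b, ] <- per_state(ta[sample.int(na, na, replace = TRUE)],
                           tb[sample.int(nb, nb, replace = TRUE)])
  }
  alpha <- (1 - level_ci) / 2
  out <- data.frame(state = states, hellinger = unname(point),
                    bi_low = NA_real_, bi_high = NA_real_,
                    n_undefined = colSums(is.na(reps)),
                    convention = convention, stringsAsFactors = FALSE)
  for (i in seq_along(states)) {
    u <- reps[!is.na(reps[, i]), i]
    if (length(u)) {
      q <- stats::quantile(u, c(alpha, 1 - alpha), type = 7)
      out$bi_low[i] <- unname(q[1]); out$bi_high[i] <- unname(q[2])
    }
  }
  rownames(out) <- NULL
  out
}

#' Difference in conditional entropy between two skill groups
#'
#' Point difference `H(group a) - H(group b)` of the conditional entropy of
#' the two groups' transition models, with a 95% interval from the same
#' paired trial-level bootstrap as [compare_flows()].
#'
#' @inheritParams compare_flows
#' @param log_base Entropy base, see [conditional_entropy()].
#' @return List with `entropy_a`, `entropy_b`, `difference`, `bi_low`,
#'   `bi_high`, `log_base`, `n_undefined`.
#' @export
entropy_difference <- function(trials_a, trials_b, level = "maneuver",
                               states = NULL, n_boot = 1000, seed = NULL,
                               level_ci = 0.95, log_base = 2,
                               include_virtual = FALSE) {
  if (length(trials_a) == 0 || length(trials_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (is.null(states)) {
    states <- sort(unique(unlist(c(extract_sequences(trials_a, level),
                                   extract_sequences(trials_b, level)))))
  }
  ent <- function(tr) {
    m <- build_transition_model(extract_sequences(tr, level), states,
                                include_virtual)
    if (m$n_transitions == 0) return(NA_real_)
    conditional_entropy(m, log_base)
  }
  ta <- canonical_order(trials_a); tb <- canonical_order(trials_b)
  ea <- ent(ta); eb <- ent(tb)
  na <- length(ta); nb <- length(tb)
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    ent(ta[sample.int(na, na, replace = TRUE)]) -
      ent(tb[sample.int(nb, nb, replace = TRUE)])
  }, numeric(1))
  u <- reps[!is.na(reps)]
  alpha <- (1 - level_ci) / 2
  q <- if (length(u)) stats::quantile(u, c(alpha, 1 - alpha), type = 7) else
    c(NA_real_, NA_real_)
  list(entropy_a = ea, entropy_b = eb, difference = ea - eb,
       bi_low = unname(q[1]), bi_high = unname(q[2]), log_base = log_base,
       n_undefined = n_boot - length(u))
}

#' Export a transition model as a Graphviz DOT state-flow graph
#'
#' One node per observed state and one directed edge per transition whose
#' probability reaches `min_edge_fraction`; the edge pen-width is
#' proportional to the fraction of the source state's outgoing transitions
#' the edge carries (the row probability). Nodes and edges are emitted in
#' lexicographic order so output is byte-stable.
#'
#' @param model A `transition_model`.
#' @param min_edge_fraction Minimum row probability for an edge to be drawn.
#' @param graph_name Graph identifier in the DOT header.
#' @param path Optional file to write to.
#' @return The DOT document as a single string (invisibly when `path` is
#'   given).
#' @export
export_stateflow_dot <- function(model, min_edge_fraction = 0,
                                 graph_name = "stateflow", path = NULL) {
  observed <- model$states[rowSums(model$counts) > 0 |
                             colSums(model$counts) > 0]
  observed <- sort(observed)
  lines <- c(sprintf("digraph %s {", graph_name),
             "  rankdir=LR;",
             "  node [shape=ellipse];",
             sprintf("  \"%s\";", observed))
  edges <- character(0)
  for (from in observed) {
    p <- model$probs[from, ]
    for (to in sort(model$states[p >= min_edge_fraction & p > 0])) {
      edges <- c(edges, sprintf(
        "  \"%s\" -> \"%s\" [penwidth=%.2f, label=\"%.2f\"];",
        from, to, 0.5 + 4.5 * p[to], p[to]))
    }
  }
  lines <- c(lines, edges, "}")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
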