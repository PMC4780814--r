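#' Write a synthetic dataset to disk in the deposited dialects
#'
#' Generates a dataset with [generate_dataset()] and writes `gestures.txt`,
#' `maneuvers.txt`, `skills.txt` (tab-delimited, as read by
#' [read_dataset_dir()]), `vocabulary.yaml`, and a `ground_truth.yaml`
#' sidecar recording the generator seed and the per-trial surgeon/class map.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Generator seed.
#' @param ... Passed to [generate_dataset()].
#' @return The generated `surg_dataset`, invisibly.
#' @export
simulate_to_dir <- function(out_dir, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_dataset(seed = seed, ...)
  ds <- gen$dataset
  g_rows <- list(); m_rows <- list(); s_rows <- list()
  man_global <- 0L
  for (tr in ds$trials) {
    m <- tr$maneuvers
    m_rows[[length(m_rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, label_raw = m$label_raw,
      incomplete = m$incomplete, stringsAsFactors = FALSE)
    g <- tr$gestures
    g_rows[[length(g_rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, label = g$label, error = g$error,
      maneuver_row = man_global + g$maneuver_ordinal + 1L,
      stringsAsFactors = FALSE)
    man_global <- man_global + nrow(m)
    sk <- tr$skill
    s_rows[[length(s_rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, experience_class = sk$experience_class,
      grs_total = sk$grs_total,
      grs1 = sk$grs_items[1], grs2 = sk$grs_items[2], grs3 = sk$grs_items[3],
      grs4 = sk$grs_items[4], grs5 = sk$grs_items[5], grs6 = sk$grs_items[6])
  }
  write_gesture_table(do.call(rbind, g_rows), file.path(out_dir, "gestures.txt"))
  write_maneuver_table(do.call(rbind, m_rows), file.path(out_dir, "maneuvers.txt"))
  write_skill_table(do.call(rbind, s_rows), file.path(out_dir, "skills.txt"))
  write_vocabulary(ds$vocabulary, file.path(out_dir, "vocabulary.yaml"))
  yaml::write_yaml(
    list(seed = seed,
         trials = lapply(seq_len(nrow(gen$ground_truth$trials)), function(i) {
           as.list(gen$ground_truth$trials[i, ])
         })),
    file.path(out_dir, "ground_truth.yaml"))
  invisible(ds)
}

#' End-to-end analysis report
#'
#' Runs the full pipeline on an assembled dataset: validation, skill-group
#' count statistics with bootstrap intervals and the interval-non-overlap
#' significance rule, Hellinger flow comparisons and the conditional-entropy
#' difference at the maneuver level and within each requested maneuver, DOT
#' state-flow files per group and level, and (when a paired second
#' annotation is supplied) sequence-level reliability. All randomness flows
#' from `seed`; repeated runs with the same inputs and seed produce
#' byte-identical files. A `manifest.json` records the resolved
#' configuration and the vocabulary hash.
#'
#' @param dataset A `surg_dataset` (validation errors abort).
#' @param out_dir Output directory.
#' @param skill_scheme Grouping scheme, see [skill_assignments()].
#' @param metrics Count metrics to tabulate.
#' @param gesture_levels Maneuvers whose within-maneuver gesture flow is
#'   compared.
#' @param n_boot,seed Bootstrap settings.
#' @param convention Hellinger convention.
#' @param log_base Entropy base.
#' @param min_edge_fraction Edge threshold for the DOT export.
#' @param paired_sequences Optional list with elements `a` and `b`: paired
#'   lists of label sequences for reliability analysis.
#' @return List with the computed tables (`group_stats`, `significance`,
#'   `flows`, `entropy`, optionally `reliability`) and `paths` of all files
#'   written, invisibly.
#' @export
run_full_report <- function(dataset, out_dir,
                            skill_scheme = "experience",
                            metrics = c("total_maneuvers",
                                        "incomplete_maneuvers", "ims_count",
                                        "total_gestures", "error_gestures"),
                            gesture_levels = c("ST", "TLK", "OLK"),
                            n_boot = 1000, seed = 1,
                            convention = "normalized", log_base = 2,
                            min_edge_fraction = 0.05,
                            paired_sequences = NULL) {
  errs <- dataset$validation[dataset$validation$severity == "error", ]
  if (nrow(errs) > 0) {
    stop("dataset failed validation:\n",
         paste(sprintf("  trial %s: %s", errs$trial_id, errs$problem),
               collapse = "\n"))
  }
  inv <- check_invariants(dataset)
  if (nrow(inv) > 0) {
    stop("dataset violates type invariants:\n",
         paste(sprintf("  trial %s: %s", inv$trial_id, inv$problem),
               collapse = "\n"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "dot"), showWarnings = FALSE)

  groups <- split_by_skill(dataset, skill_scheme)
  gstats <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    group_mean_bi(dataset, metrics[i], skill_scheme, n_boot,
                  seed = seed + 100 * i)
  }))
  sig <- do.call(rbind, lapply(metrics, function(m) {
    rows <- gstats[gstats$metric == m, ]
    pairs <- utils::combn(rows$group, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(pr) {
      fl <- significance_flag(rows[rows$group == pr[1], ],
                              rows[rows$group == pr[2], ])
      data.frame(metric = m, group_a = pr[1], group_b = pr[2],
                 significant = fl$significant,
                 directions = paste(fl$directions, collapse = "; "),
                 stringsAsFactors = FALSE)
    }))
  }))

  levels_all <- c("maneuver", paste0("gesture:", gesture_levels))
  cmp_groups <- intersect(c("expert", "novice"), names(groups))
  flows <- NULL; entro <- NULL
  if (length(cmp_groups) == 2) {
    ga <- groups[["expert"]]; gb <- groups[["novice"]]
    flows <- do.call(rbind, lapply(seq_along(levels_all), function(i) {
      fc <- compare_flows(ga, gb, levels_all[i], n_boot = n_boot,
                          seed = seed + 1000 + i, convention = convention,
                          include_virtual = TRUE)
      cbind(level = levels_all[i], fc, stringsAsFactors = FALSE)
    }))
    entro <- do.call(rbind, lapply(seq_along(levels_all), function(i) {
      ed <- entropy_difference(ga, gb, levels_all[i], n_boot = n_boot,
                               seed = seed + 2000 + i, log_base = log_base)
      data.frame(level = levels_all[i], entropy_expert = ed$entropy_a,
                 entropy_novice = ed$entropy_b, difference = ed$difference,
                 bi_low = ed$bi_low, bi_high = ed$bi_high,
                 log_base = log_base, stringsAsFactors = FALSE)
    }))
  }

  for (gname in names(groups)) {
    for (lev in levels_all) {
      seqs <- extract_sequences(groups[[gname]], lev)
      if (length(seqs) == 0) next
      model <- build_transition_model(seqs)
      export_stateflow_dot(
        model, min_edge_fraction,
        graph_name = gsub("[^A-Za-z0-9_]", "_", paste0(gname, "_", lev)),
        path = file.path(out_dir, "dot",
                         paste0(gname, "_", gsub(":", "_", lev), ".dot")))
    }
  }

  rel <- NULL
  if (!is.null(paired_sequences)) {
    rel <- mean_ld_with_ci(paired_sequences$a, paired_sequences$b,
                           n_boot = n_boot, seed = seed + 3000)
  }

  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  paths <- c(wcsv(gstats, "group_stats.csv"), wcsv(sig, "significance.csv"))
  if (!is.null(flows)) paths <- c(paths, wcsv(flows, "flow_comparisons.csv"))
  if (!is.null(entro)) paths <- c(paths, wcsv(entro, "entropy_comparisons.csv"))
  if (!is.null(rel)) {
    rtab <- data.frame(mean_nld_per10 = rel$mean_nld, ci_low = rel$ci_low,
                       ci_high = rel$ci_high, n_trials = nrow(rel$per_trial),
                       reference = rel$reference)
    paths <- c(paths, wcsv(rtab, "reliability.csv"))
  }

  manifest <- list(
    seed = seed, n_boot = n_boot, skill_scheme = skill_scheme,
    hellinger_convention = convention, entropy_log_base = log_base,
    min_edge_fraction = min_edge_fraction,
    n_trials = length(dataset$trials),
    vocabulary_hash = vocabulary_hash(dataset$vocabulary),
    package_version = as.character(utils::packageVersion("surgflow"))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(group_stats = gstats, significance = sig, flows = flows,
                 entropy = entro, reliability = rel,
                 paths = c(paths, mp)))
}
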