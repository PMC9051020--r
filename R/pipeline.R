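## End-to-end pipeline: simulate (optional) -> OCT stage -> SLP stage ->
## cohort statistics -> summary JSON + Markdown report.

#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key: value` or `key = value`; `#` starts a comment.
#' Either `manifest` (one or more comma-separated manifest paths) or a
#' simulation block (`cohort1_n`, `cohort1_mode`, optionally `cohort2_*`)
#' must be present, not both. `sim_*` keys override [sim_config()]
#' defaults; `seed` drives every source of randomness; `statistic` selects
#' the headline intensity statistic (`ring_mean` or `cross_amplitude`).
#'
#' @param path Config file path.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  cfg <- stats::setNames(lapply(kv, function(m) {
    v <- trimws(m[3])
    suppressWarnings(if (!is.na(as.numeric(v))) as.numeric(v) else v)
  }), vapply(kv, `[[`, character(1), 2))
  as_pipeline_config(cfg)
}

as_pipeline_config <- function(cfg) {
  has_manifest <- !is.null(cfg$manifest)
  has_sim <- !is.null(cfg$cohort1_n)
  if (has_manifest == has_sim) {
    stop("config must provide exactly one input source: ",
         "'manifest' or a cohort simulation block")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$statistic <- cfg$statistic %||% "ring_mean"
  if (!cfg$statistic %in% c("ring_mean", "cross_amplitude")) {
    stop("statistic must be ring_mean or cross_amplitude")
  }
  cfg$log_level <- cfg$log_level %||% "info"
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) {
    message(sprintf(...))
  }
}

sim_config_from_pipeline <- function(cfg) {
  keys <- grep("^sim_", names(cfg), value = TRUE)
  overrides <- stats::setNames(cfg[keys], sub("^sim_", "", keys))
  overrides <- overrides[names(overrides) %in% names(formals(sim_config))]
  do.call(sim_config, c(overrides, list(seed = cfg$seed)))
}

## Run OCT + SLP stages for every subject of one manifest; returns the
## subject_result list (named by subject id) and a drop log.
process_cohort <- function(manifest, cfg, out_dir) {
  base <- manifest$base_dir
  results <- list()
  dropped <- character(0)
  for (subj in manifest$subjects) {
    scans <- lapply(subj$scans, read_scan, base_dir = base)
    thickness <- withCallingHandlers(
      oct_subject_thickness(scans),
      warning = function(w) {
        pipe_log(cfg, "  %s: %s", subj$id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(thickness, "qc_drop")) {
      pipe_log(cfg, "  %s dropped: %s", subj$id, thickness$reason)
      dropped <- c(dropped, sprintf("%s: %s", subj$id, thickness$reason))
      next
    }
    map <- read_retardation_map(file.path(base, subj$slp$image))
    if (!qc_filter_slp(map$quality_score)) {
      reason <- sprintf("SLP quality %.1f fails the >=8 criterion",
                        map$quality_score)
      pipe_log(cfg, "  %s dropped: %s", subj$id, reason)
      dropped <- c(dropped, sprintf("%s: %s", subj$id, reason))
      next
    }
    center <- locate_macular_center(map)
    tab <- slp_subject_profile(map, center)
    tab <- cbind(subject = subj$id, thickness_px = thickness$values, tab)
    tab <- tab[, c("subject", "eccentricity_deg", "thickness_px",
                   "ring_mean", "cross_amplitude", "fit_r2", "mode")]
    write_subject_profile(tab, file.path(
      out_dir, sprintf("%s_%s_profile.csv", manifest$cohort_label, subj$id)))
    intensity <- ecc_profile(tab[[cfg$statistic]], "intensity")
    results[[subj$id]] <- subject_result(subj$id, thickness, intensity)
    pipe_log(cfg, "  %s: r = %.3f (center %.1f, %.1f)", subj$id,
             results[[subj$id]]$r, center[1], center[2])
  }
  list(results = results, dropped = dropped)
}

summary_as_list <- function(s) {
  list(label = s$label, n_subjects = s$n_subjects,
       thickness_median = s$thickness_median,
       thickness_q25 = s$thickness_q25, thickness_q75 = s$thickness_q75,
       intensity_median = s$intensity_median,
       intensity_q25 = s$intensity_q25, intensity_q75 = s$intensity_q75,
       cov_by_eccentricity = as.numeric(s$cov_by_eccentricity),
       eccentricity_deg = canonical_grid(),
       subject_r = as.numeric(s$subject_r),
       mean_r = s$mean_r, r_squared = s$r_squared)
}

#' Run the full pipeline
#'
#' Simulates cohorts when the configuration requests it (otherwise reads
#' existing manifests), applies the OCT and SLP quality filters and
#' stages per subject, computes cohort statistics, and writes per-subject
#' profile CSVs, a per-cohort summary JSON, a Table-1-style CoV CSV, and
#' a Markdown report. Hard errors (malformed manifest, every subject
#' failing QC) propagate; QC-dropped subjects are logged and decrement
#' the cohort size.
#'
#' @param config A `pipeline_config` (from [read_pipeline_config()]) or a
#'   named list with the same keys.
#' @param out_dir Output directory.
#' @return Invisibly, a list of output paths (`summaries`, `cov_tables`,
#'   `report`) plus the in-memory `cohort_summaries` and `comparisons`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else as_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifests <- if (!is.null(cfg$manifest)) {
    paths <- trimws(strsplit(as.character(cfg$manifest), ",")[[1]])
    lapply(paths, read_manifest)
  } else {
    sim <- sim_config_from_pipeline(cfg)
    specs <- list(list(n = cfg$cohort1_n, mode = cfg$cohort1_mode,
                       label = "cohort1"))
    if (!is.null(cfg$cohort2_n)) {
      specs <- c(specs, list(list(n = cfg$cohort2_n, mode = cfg$cohort2_mode,
                                  label = "cohort2")))
    }
    lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      pipe_log(cfg, "simulating %s: n = %d, %s compensation", sp$label,
               sp$n, sp$mode)
      path <- simulate_cohort(sim, sp$n, sp$mode,
                              seed = derive_seed(cfg$seed, i),
                              out_dir = file.path(out_dir, "sim", sp$label),
                              cohort_label = sp$label)
      read_manifest(path)
    })
  }

  summaries <- list()
  results_by_cohort <- list()
  summary_paths <- character(0)
  cov_paths <- character(0)
  dropped_all <- character(0)
  for (m in manifests) {
    pipe_log(cfg, "processing %s (%d subjects, %s compensation)",
             m$cohort_label, length(m$subjects), m$mode)
    pc <- process_cohort(m, cfg, out_dir)
    if (length(pc$results) == 0) {
      stop("all subjects of ", m$cohort_label, " failed quality control")
    }
    s <- summarize_cohort(pc$results, label = m$cohort_label)
    summaries[[m$cohort_label]] <- s
    results_by_cohort[[m$cohort_label]] <- pc$results
    dropped_all <- c(dropped_all, pc$dropped)

    sp <- file.path(out_dir, sprintf("%s_summary.json", m$cohort_label))
    write_json_file(summary_as_list(s), sp)
    summary_paths <- c(summary_paths, sp)
    cp <- file.path(out_dir, sprintf("%s_cov.csv", m$cohort_label))
    utils::write.csv(data.frame(eccentricity_deg = canonical_grid(),
                                cov_cohort = as.numeric(s$cov_by_eccentricity)),
                     cp, row.names = FALSE, quote = FALSE)
    cov_paths <- c(cov_paths, cp)
  }

  comparisons <- NULL
  if (length(summaries) == 2) {
    pooled <- function(results, field) {
      as.numeric(vapply(results, function(s) s[[field]]$values,
                        numeric(length(canonical_grid()))))
    }
    ra <- results_by_cohort[[1]]
    rb <- results_by_cohort[[2]]
    comparisons <- list(
      thickness_mw = mann_whitney(pooled(ra, "thickness"),
                                  pooled(rb, "thickness")),
      intensity_mw = mann_whitney(pooled(ra, "intensity"),
                                  pooled(rb, "intensity")),
      cov_mw = mann_whitney(
        as.numeric(summaries[[1]]$cov_by_eccentricity),
        as.numeric(summaries[[2]]$cov_by_eccentricity)))
    overall <- fisher_average(c(summaries[[1]]$subject_r,
                                summaries[[2]]$subject_r))
    comparisons$overall_mean_r <- overall$mean_r
    comparisons$overall_r_squared <- overall$r_squared
    write_json_file(comparisons, file.path(out_dir, "comparisons.json"))
  }

  report <- write_report(summaries, results_by_cohort, comparisons,
                         dropped_all, cfg, out_dir)
  pipe_log(cfg, "report written to %s", report)
  invisible(list(summaries = summary_paths, cov_tables = cov_paths,
                 report = report, cohort_summaries = summaries,
                 comparisons = comparisons))
}

fmt <- function(x) sprintf("%.4f", x)

write_report <- function(summaries, results_by_cohort, comparisons, dropped,
                         cfg, out_dir) {
  grid <- canonical_grid()
  lines <- c("# HFL thickness vs. macular phase retardation", "",
             sprintf("Headline intensity statistic: `%s`", cfg$statistic), "")
  for (s in summaries) {
    res <- results_by_cohort[[s$label]]
    lines <- c(lines, sprintf("## %s (n = %d)", s$label, s$n_subjects), "",
      sprintf("- HFL thickness median [q25, q75]: %s [%s, %s] px",
              fmt(s$thickness_median), fmt(s$thickness_q25),
              fmt(s$thickness_q75)),
      sprintf("- Pixel intensity median [q25, q75]: %s [%s, %s]",
              fmt(s$intensity_median), fmt(s$intensity_q25),
              fmt(s$intensity_q75)),
      sprintf("- Fisher-averaged R = %s, R^2 = %s", fmt(s$mean_r),
              fmt(s$r_squared)), "",
      "| Eccentricity (deg) | Mean thickness (px) | Mean intensity | CoV (%) |",
      "|---|---|---|---|",
      vapply(seq_along(grid), function(i) {
        sprintf("| %.2f | %s | %s | %s |", grid[i],
                fmt(mean(vapply(res, function(r) r$thickness$values[i],
                                numeric(1)))),
                fmt(mean(vapply(res, function(r) r$intensity$values[i],
                                numeric(1)))),
                fmt(s$cov_by_eccentricity[i]))
      }, character(1)), "")
  }
  if (!is.null(comparisons)) {
    lines <- c(lines, "## Cohort comparisons (Mann-Whitney, two-sided)", "",
      sprintf("- Thickness: U = %s, p = %s",
              fmt(comparisons$thickness_mw$U), fmt(comparisons$thickness_mw$p)),
      sprintf("- Intensity: U = %s, p = %s",
              fmt(comparisons$intensity_mw$U), fmt(comparisons$intensity_mw$p)),
      sprintf("- Per-ring CoV: U = %s, p = %s",
              fmt(comparisons$cov_mw$U), fmt(comparisons$cov_mw$p)),
      sprintf("- Combined-cohort Fisher-averaged R^2 = %s",
              fmt(comparisons$overall_r_squared)), "")
  }
  if (length(dropped)) {
    lines <- c(lines, "## Subjects removed by quality control", "",
               paste0("- ", dropped), "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  path
}
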