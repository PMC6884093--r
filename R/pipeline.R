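#' Pipeline configuration
#'
#' Bundles the fixed analysis choices: the biomarker panel, the diagnosis
#' grouping (PPMS and SPMS merge into PMS by default), the candidate
#' covariates and selection alpha, Box-Cox settings, the cluster mode
#' (`"frozen"` reproduces the reference partition; `"derived"` re-derives it
#' from the residual correlations at `r_threshold`), and the sub-cohorts
#' over which cross-compartment and severity correlations are reported.
#'
#' @param panel Biomarker panel tibble.
#' @param grouping Named character vector mapping raw diagnosis labels to
#'   analysis groups.
#' @param covariates Candidate covariate columns for [fit_adjustment()].
#' @param selection_alpha Covariate-selection threshold.
#' @param lambda_grid,lambda_fixed Box-Cox settings, see
#'   [standardize_biomarkers()].
#' @param cluster_mode `"frozen"` or `"derived"`.
#' @param r_threshold Edge threshold for derived clusters.
#' @param subcohorts Named list of analysis-group subsets for the
#'   correlation tables.
#' @param icc_flag Stability-report ICC threshold.
#' @param alpha Significance level used when reports flag results.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = default_panel(),
                            grouping = c(HD = "HD", RRMS = "RRMS",
                                         PPMS = "PMS", SPMS = "PMS"),
                            covariates = c("age", "sex", "race"),
                            selection_alpha = 0.05,
                            lambda_grid = seq(-3, 3, by = 0.01),
                            lambda_fixed = NULL,
                            cluster_mode = c("frozen", "derived"),
                            r_threshold = 0.3,
                            subcohorts = list(MS = c("RRMS", "PMS"),
                                              RRMS = "RRMS", PMS = "PMS"),
                            icc_flag = 0.8, alpha = 0.05) {
  cluster_mode <- match.arg(cluster_mode)
  validate_panel(panel)
  cfg <- list(panel = panel, grouping = grouping, covariates = covariates,
              selection_alpha = selection_alpha, lambda_grid = lambda_grid,
              lambda_fixed = lambda_fixed, cluster_mode = cluster_mode,
              r_threshold = r_threshold, subcohorts = subcohorts,
              icc_flag = icc_flag, alpha = alpha)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file whose top-level keys are [pipeline_config()]
#' arguments (`panel` as a list of records; `grouping` and `lambda_fixed`
#' as maps). Unknown keys are an error. A copy of the shipped defaults is
#' at `system.file("extdata", "reference_defaults.yaml", package = "inflaclust")`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$panel)) raw$panel <- dplyr::bind_rows(raw$panel)
  for (f in c("grouping", "lambda_fixed")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$lambda_grid) && length(raw$lambda_grid) == 3 &&
      !is.null(names(raw$lambda_grid))) {
    raw$lambda_grid <- seq(raw$lambda_grid[["from"]],
                           raw$lambda_grid[["to"]],
                           by = raw$lambda_grid[["by"]])
  }
  do.call(pipeline_config, raw)
}

#' Read and validate a cohort file
#'
#' Reads a CSV or TSV visit table (empty strings and `"NA"` parse as
#' missing), checks the required columns (`subject_id`, `diagnosis`,
#' `visit`), validates diagnosis labels, and logs a schema report (rows,
#' subjects, per-column missingness) as a message.
#'
#' @param path Path to a delimited file; tab-separated when the extension
#'   is `.tsv` or `.txt`.
#' @param allowed_diagnoses Valid diagnosis labels.
#' @param quiet Suppress the schema report.
#' @return A tibble.
#' @export
read_cohort <- function(path,
                        allowed_diagnoses = c("HD", "RRMS", "PPMS", "SPMS"),
                        quiet = FALSE) {
  sep_tab <- grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)
  cohort <- if (sep_tab) {
    readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                    progress = FALSE)
  } else {
    readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                    progress = FALSE)
  }
  required <- c("subject_id", "diagnosis", "visit")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(cohort$diagnosis) & !(cohort$diagnosis %in% allowed_diagnoses)
  if (any(bad)) {
    stop("unknown diagnosis value(s) in rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(cohort$diagnosis[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (!quiet) {
    miss <- vapply(cohort, function(x) mean(is.na(x)), numeric(1))
    message("cohort: ", nrow(cohort), " visits, ",
            length(unique(cohort$subject_id)), " subjects; missingness ",
            paste0(names(miss)[miss > 0], "=",
                   sprintf("%.0f%%", 100 * miss[miss > 0]),
                   collapse = " "))
  }
  cohort
}

#' Write a cohort (and ground truth) to disk
#'
#' @param cohort Visit table.
#' @param path Output CSV path.
#' @param truth Optional ground-truth list from [generate_cohort()];
#'   written as a JSON sidecar `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth = NULL) {
  readr::write_csv(cohort, path, na = "NA")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' @noRd
pairwise_correlations <- function(d, analytes) {
  if (length(analytes) < 2) {
    return(tibble::tibble(analyte_1 = character(), analyte_2 = character(),
                          r = numeric(), n = integer()))
  }
  pairs <- utils::combn(sort(analytes), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a1 <- pairs[1, i]; a2 <- pairs[2, i]
    ok <- !is.na(d[[a1]]) & !is.na(d[[a2]])
    r <- if (sum(ok) >= 3) stats::cor(d[[a1]][ok], d[[a2]][ok]) else NA_real_
    tibble::tibble(analyte_1 = a1, analyte_2 = a2, r = r, n = sum(ok))
  })
}

#' Run the full composite-biomarker analysis
#'
#' Orchestrates the pipeline end to end: visit averaging with ICC
#' screening, Box-Cox + Z standardization, covariate adjustment and
#' residualization, polarity flip, cluster definition (frozen or derived)
#' and scoring, marker- and cluster-level group comparisons, blood-by-CSF
#' Pearson correlations and cluster-by-severity Spearman correlations per
#' sub-cohort, all with per-family BH-FDR adjustment. Deterministic:
#' identical inputs give identical outputs.
#'
#' @param cohort Long-format visit table (see [read_cohort()] for the
#'   schema).
#' @param config A [pipeline_config()].
#' @return A list of class `inflaclust_report`: `icc_report`, `transform`,
#'   `adjustment` (selection table), `markers_group`, `cluster_definitions`,
#'   `cluster_correlations`, `cluster_groups`, `blood_csf`, `severity`,
#'   `scores` (per-patient cluster scores), `residuals`, and `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  panel <- config$panel
  present_dx <- unique(as.character(cohort$diagnosis))
  uncovered <- setdiff(present_dx, names(config$grouping))
  if (length(uncovered) > 0) {
    stop("grouping does not cover diagnosis value(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  cohort$diagnosis <- unname(config$grouping[as.character(cohort$diagnosis)])

  pre <- stage("preprocess", summarize_subjects(cohort, panel,
                                                icc_flag = config$icc_flag))
  std <- stage("standardize", standardize_biomarkers(
    pre$summary, panel, lambda_grid = config$lambda_grid,
    lambda_fixed = config$lambda_fixed))
  adj <- stage("adjust", fit_adjustment(
    std$scores, panel, covariates = config$covariates,
    alpha = config$selection_alpha))
  resid_raw <- stage("residualize", residualize(std$scores, adj))
  resid <- stage("polarity", apply_polarity(resid_raw, panel))

  defs <- stage("cluster", {
    if (config$cluster_mode == "frozen") {
      fc <- frozen_clusters()
      fc[fc$compartment %in% unique(panel$compartment) &
           vapply(fc$members, function(m) all(m %in% names(resid)),
                  logical(1)), ]
    } else {
      dplyr::bind_rows(
        derive_clusters(resid, panel, "blood", "all",
                        r_threshold = config$r_threshold),
        derive_clusters(resid, panel, "csf", "ms_only",
                        r_threshold = config$r_threshold))
    }
  })
  scores <- stage("score", score_clusters(resid, defs))

  blood_analytes <- intersect(panel$analyte[panel$compartment == "blood"],
                              names(resid))
  csf_analytes <- intersect(panel$analyte[panel$compartment == "csf"],
                            names(resid))
  ms_resid <- resid[resid$diagnosis != "HD", , drop = FALSE]
  cluster_correlations <- dplyr::bind_rows(
    dplyr::mutate(pairwise_correlations(resid, blood_analytes),
                  compartment = "blood", population = "all"),
    dplyr::mutate(pairwise_correlations(ms_resid, csf_analytes),
                  compartment = "csf", population = "ms_only"))

  # marker-level HD vs MS comparison on pre-flip residuals (native direction)
  hd_ms <- dplyr::mutate(
    resid_raw, hd_ms = ifelse(.data$diagnosis == "HD", "HD", "MS"))
  analytes <- intersect(panel$analyte, names(resid_raw))
  markers_group <- stage("associate", compare_groups(
    hd_ms, analytes, group = "hd_ms", method = "anova",
    family = "markers_hd_vs_ms"))

  scores_hd_ms <- dplyr::mutate(
    scores, hd_ms = ifelse(.data$diagnosis == "HD", "HD", "MS"))
  cluster_groups <- stage("associate", compare_groups(
    scores_hd_ms, defs$cluster, group = "hd_ms", method = "t",
    family = "clusters_hd_vs_ms"))

  blood_defs <- defs$cluster[defs$compartment == "blood"]
  csf_defs <- defs$cluster[defs$compartment == "csf"]
  sev <- intersect(severity_cols(), names(pre$summary))
  scores_sev <- dplyr::left_join(
    scores, pre$summary[, c("subject_id", sev), drop = FALSE],
    by = "subject_id")

  blood_csf <- list()
  severity <- list()
  for (nm in names(config$subcohorts)) {
    sub <- scores_sev[scores_sev$diagnosis %in% config$subcohorts[[nm]], ,
                      drop = FALSE]
    if (nrow(sub) == 0) next
    blood_csf[[nm]] <- dplyr::mutate(stage("associate", correlate(
      sub, blood_defs, csf_defs, method = "pearson",
      family = paste0("blood_csf_", nm))), cohort = nm)
    if (length(sev) > 0) {
      severity[[nm]] <- dplyr::mutate(stage("associate", correlate(
        sub, defs$cluster, sev, method = "spearman",
        family = paste0("severity_", nm))), cohort = nm)
    }
  }

  manifest <- list(
    package = "inflaclust",
    version = as.character(utils::packageVersion("inflaclust")),
    config_hash = rlang::hash(config),
    input_hash = rlang::hash(cohort),
    n_visits = nrow(cohort),
    n_subjects = nrow(pre$summary),
    cluster_mode = config$cluster_mode
  )

  out <- list(
    icc_report = pre$icc_report,
    transform = std$model,
    adjustment = adj$selection,
    markers_group = markers_group,
    cluster_definitions = defs,
    cluster_correlations = cluster_correlations,
    cluster_groups = cluster_groups,
    blood_csf = dplyr::bind_rows(blood_csf),
    severity = dplyr::bind_rows(severity),
    scores = scores,
    residuals = resid,
    severity_table = pre$summary[, c("subject_id", "diagnosis", sev),
                                 drop = FALSE],
    manifest = manifest
  )
  class(out) <- "inflaclust_report"
  out
}

#' @export
print.inflaclust_report <- function(x, ...) {
  cat("inflaclust report:", x$manifest$n_subjects, "subjects,",
      x$manifest$n_visits, "visits;", nrow(x$cluster_definitions),
      "clusters (", x$manifest$cluster_mode, ")\n", sep = " ")
  cat("significant (adjusted p < 0.05):",
      sum(x$markers_group$p_adjusted < 0.05), "markers HD-vs-MS;",
      sum(x$cluster_groups$p_adjusted < 0.05), "clusters HD-vs-MS;",
      sum(x$blood_csf$p_adjusted < 0.05, na.rm = TRUE), "blood-CSF pairs;",
      sum(x$severity$p_adjusted < 0.05, na.rm = TRUE), "severity pairs\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `inflaclust_report`.
#' @param ... Unused.
#' @export
glance.inflaclust_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$manifest$n_subjects,
    n_visits = x$manifest$n_visits,
    n_clusters = nrow(x$cluster_definitions),
    n_blood_csf_pairs = nrow(x$blood_csf[x$blood_csf$cohort ==
                                           x$blood_csf$cohort[1], ]),
    sig_markers = sum(x$markers_group$p_adjusted < 0.05),
    sig_clusters = sum(x$cluster_groups$p_adjusted < 0.05)
  )
}

#' Write a report bundle to disk
#'
#' Emits one TSV per report table plus a single JSON bundle and the run
#' manifest. Output is deterministic for identical inputs.
#'
#' @param report An `inflaclust_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("icc_report", "transform", "adjustment", "markers_group",
              "cluster_definitions", "cluster_correlations",
              "cluster_groups", "blood_csf", "severity", "scores",
              "severity_table")
  flat <- list()
  for (nm in tables) {
    tbl <- report[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0) next
    if ("members" %in% names(tbl)) {
      tbl$members <- vapply(tbl$members, paste, character(1), collapse = ";")
    }
    readr::write_tsv(tbl, file.path(dir, paste0(nm, ".tsv")))
    flat[[nm]] <- tbl
  }
  jsonlite::write_json(flat, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Parameter-recovery and calibration study
#'
#' Repeatedly generates cohorts from each scenario config, runs the
#' pipeline, and summarises how well the analysis recovers the generating
#' truth: the fraction of replicates in which data-driven clustering
#' recovers the true partition exactly (adjusted Rand index 1), bias and
#' RMSE of the HD-vs-MS diagnosis shifts, the median estimated severity
#' coupling, and the per-family false-positive rate (any adjusted p < 0.05)
#' for the cross-compartment family — the calibration check for null
#' scenarios.
#'
#' @param scenarios Named list of [synthetic_config()] objects.
#' @param reps Replicates per scenario; 0 returns an empty, fully typed
#'   summary.
#' @param seed Base seed; replicate r of scenario s uses
#'   `seed + 1000 * s + r`.
#' @param lambda_grid Box-Cox grid used in the replicated pipeline (a
#'   coarser default keeps the study fast; lambda precision does not drive
#'   any of the summarised quantities).
#' @param metrics Which summaries to compute; dropping `"partition"` skips
#'   the data-driven re-clustering, which dominates the cost of large
#'   calibration studies.
#' @return A tibble, one row per scenario.
#' @export
run_recovery <- function(scenarios, reps, seed = 1L,
                         lambda_grid = seq(-3, 3, by = 0.05),
                         metrics = c("partition", "diagnosis", "severity",
                                     "fp")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if ("partition" %in% metrics &&
      !requireNamespace("mclust", quietly = TRUE)) {
    stop("run_recovery needs the 'mclust' package for the adjusted Rand index",
         call. = FALSE)
  }
  empty <- tibble::tibble(
    scenario = character(), reps = integer(),
    partition_recovery = numeric(), diagnosis_bias = numeric(),
    diagnosis_rmse = numeric(), severity_rho_median = numeric(),
    blood_csf_fp_rate = numeric(), severity_fp_rate = numeric())
  if (reps == 0 || length(scenarios) == 0) return(empty)
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }

  purrr::imap_dfr(scenarios, function(cfg, nm) {
    s_idx <- match(nm, names(scenarios))
    ari_hits <- logical(reps)
    dx_err <- list()
    sev_rho <- rep(NA_real_, reps)
    fp_bc <- logical(reps)
    fp_sev <- logical(reps)
    for (r in seq_len(reps)) {
      cfg_r <- cfg
      cfg_r$seed <- as.integer(seed + 1000L * s_idx + r)
      sim <- generate_cohort(cfg_r)
      pre <- summarize_subjects(sim$cohort, cfg$panel)
      std <- standardize_biomarkers(pre$summary, cfg$panel,
                                    lambda_grid = lambda_grid)
      adj <- fit_adjustment(std$scores, cfg$panel)
      resid <- apply_polarity(residualize(std$scores, adj), cfg$panel)

      # partition recovery via data-driven clustering in both compartments
      derived <- if (!"partition" %in% metrics) NULL else
        tryCatch(dplyr::bind_rows(
        derive_clusters(resid, cfg$panel, "blood", "all"),
        derive_clusters(resid, cfg$panel, "csf", "ms_only")),
        error = function(e) NULL)
      if (!is.null(derived)) {
        est <- stats::setNames(
          rep(derived$cluster, lengths(derived$members)),
          unlist(derived$members))
        truth_part <- stats::setNames(sim$truth$partition$cluster,
                                      sim$truth$partition$analyte)
        keys <- names(truth_part)
        ari_hits[r] <- isTRUE(all.equal(
          mclust::adjustedRandIndex(est[keys], truth_part[keys]), 1))
      }

      # diagnosis-shift recovery: residual MS - HD means vs truth
      de <- cfg$diagnosis_effects
      if ("diagnosis" %in% metrics && nrow(de) > 0) {
        truth_shift <- de |>
          dplyr::group_by(.data$analyte) |>
          dplyr::summarise(shift = mean(.data$shift), .groups = "drop")
        is_hd <- resid$diagnosis == "HD"
        est_shift <- vapply(truth_shift$analyte, function(a) {
          mean(resid[[a]][!is_hd], na.rm = TRUE) -
            mean(resid[[a]][is_hd], na.rm = TRUE)
        }, numeric(1))
        dx_err[[r]] <- est_shift - truth_shift$shift
      }

      # severity-coupling recovery and family false positives
      scores <- score_clusters(resid, frozen_clusters())
      sev_cols <- intersect(severity_cols(), names(pre$summary))
      scores <- dplyr::left_join(
        scores, pre$summary[, c("subject_id", sev_cols)], by = "subject_id")
      ms <- scores[scores$diagnosis != "HD", , drop = FALSE]
      if ("severity" %in% metrics &&
          length(cfg$severity_coupling) > 0 && "msss" %in% sev_cols) {
        target <- names(cfg$severity_coupling)[1]
        ok <- !is.na(ms[[target]]) & !is.na(ms$msss)
        if (sum(ok) >= 3) {
          sev_rho[r] <- stats::cor(ms[[target]][ok], ms$msss[ok],
                                   method = "spearman")
        }
      }
      if ("fp" %in% metrics) {
        bc <- correlate(ms, frozen_clusters()$cluster[1:3],
                        frozen_clusters()$cluster[4:7],
                        method = "pearson", family = "blood_csf")
        fp_bc[r] <- any(bc$p_adjusted < 0.05, na.rm = TRUE)
        if (length(sev_cols) > 0) {
          sv <- correlate(ms, frozen_clusters()$cluster, sev_cols,
                          method = "spearman", family = "severity")
          fp_sev[r] <- any(sv$p_adjusted < 0.05, na.rm = TRUE)
        }
      }
    }
    errs <- unlist(dx_err)
    tibble::tibble(
      scenario = nm, reps = reps,
      partition_recovery = mean(ari_hits),
      diagnosis_bias = if (length(errs)) mean(errs) else NA_real_,
      diagnosis_rmse = if (length(errs)) sqrt(mean(errs^2)) else NA_real_,
      severity_rho_median = stats::median(sev_rho, na.rm = TRUE),
      blood_csf_fp_rate = mean(fp_bc),
      severity_fp_rate = mean(fp_sev))
  })
}
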