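#' One-way random-effects intraclass correlation
#'
#' Measurement stability of a biomarker across repeated visits, computed
#' from the one-way ANOVA mean squares with the standard unbalanced-design
#' correction: `ICC = (MSB - MSW) / (MSB + (k0 - 1) * MSW)` with
#' `k0 = (N - sum(n_i^2) / N) / (a - 1)` for `a` subjects with `n_i`
#' observations each. Visits are treated as exchangeable repeated measures
#' (no visit fixed structure), so the one-way model applies. The estimate
#' may be negative and is reported unclipped. Subjects with a single visit
#' contribute to the between-subject term only.
#'
#' @param data A data frame of repeated measurements.
#' @param subject,value Column names (strings) of the subject identifier and
#'   measurement.
#' @return A one-row tibble: `icc`, `n_subjects`, `n_obs`, `k0`, `msb`, `msw`.
#' @examples
#' d <- data.frame(subject = rep(c("A", "B", "C"), each = 2),
#'                 value = c(1, 1, 5, 5, 9, 9))
#' compute_icc(d)$icc  # 1: all variance is between subjects
#' @export
compute_icc <- function(data, subject = "subject_id", value = "value") {
  y <- data[[value]]
  g <- as.character(data[[subject]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- g[keep]
  ni <- table(g)
  a <- length(ni)
  n_total <- length(y)
  if (a < 2) {
    stop("ICC undefined: fewer than 2 subjects with observations",
         call. = FALSE)
  }
  if (!any(ni >= 2)) {
    stop("ICC undefined: no subject has 2 or more visits", call. = FALSE)
  }
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ssb <- sum(as.numeric(ni) * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (n_total - a)
  k0 <- (n_total - sum(as.numeric(ni)^2) / n_total) / (a - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  tibble::tibble(icc = icc, n_subjects = a, n_obs = n_total,
                 k0 = k0, msb = msb, msw = msw)
}

#' Collapse visits to one row per subject
#'
#' Averages each biomarker over all non-missing visits per subject
#' (averaging is unconditional; analytes whose ICC is at or below
#' `icc_flag` are flagged in the stability report, not excluded), takes
#' covariates as the across-visit mean age and the first sex/race, and takes
#' each severity score from the chronologically most recent visit where it
#' is non-missing.
#'
#' @param cohort Long-format visit table with `subject_id`, `diagnosis`,
#'   `visit`, covariates, panel analytes and (optionally) severity columns.
#' @param panel Biomarker panel, see [default_panel()].
#' @param icc_flag ICC threshold below which an analyte is flagged as
#'   unstable in the report (default 0.8).
#' @return A list: `summary` (one row per subject, analyte means plus
#'   `<analyte>_n` visit counts and most-recent severity) and `icc_report`
#'   (per-analyte ICC with a `stable` flag; `NA` ICC where undefined).
#' @export
summarize_subjects <- function(cohort, panel = default_panel(),
                               icc_flag = 0.8) {
  validate_panel(panel)
  analytes <- intersect(panel$analyte, names(cohort))
  if (length(analytes) == 0) {
    stop("cohort contains no panel analytes", call. = FALSE)
  }
  if (anyDuplicated(cohort[, c("subject_id", "visit")])) {
    dup <- cohort[duplicated(cohort[, c("subject_id", "visit")]), ]
    stop("duplicate (subject_id, visit) keys, e.g. subject ",
         dup$subject_id[1], " visit ", dup$visit[1], call. = FALSE)
  }

  icc_report <- purrr::map_dfr(analytes, function(a) {
    d <- cohort[!is.na(cohort[[a]]), c("subject_id", a)]
    names(d)[2] <- "value"
    res <- tryCatch(compute_icc(d),
                    error = function(e) tibble::tibble(
                      icc = NA_real_, n_subjects = length(unique(d$subject_id)),
                      n_obs = nrow(d), k0 = NA_real_,
                      msb = NA_real_, msw = NA_real_))
    dplyr::mutate(res, analyte = a, .before = 1)
  })
  icc_report$stable <- !is.na(icc_report$icc) & icc_report$icc > icc_flag

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  first_chr <- function(x) as.character(x[1])
  sev <- intersect(severity_cols(), names(cohort))

  summary <- cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$visit, .by_group = TRUE) |>
    dplyr::summarise(
      diagnosis = first_chr(.data$diagnosis),
      dplyr::across(dplyr::any_of("age"), mean_or_na),
      dplyr::across(dplyr::any_of(c("sex", "race")), first_chr),
      dplyr::across(dplyr::all_of(analytes),
                    list(mean = mean_or_na,
                         n = ~sum(!is.na(.x))),
                    .names = "{.col}__{.fn}"),
      dplyr::across(dplyr::all_of(sev), last_non_missing),
      .groups = "drop"
    )
  names(summary) <- sub("__mean$", "", names(summary))
  names(summary) <- sub("__n$", "_n", names(summary))
  list(summary = summary, icc_report = icc_report)
}

#' @noRd
last_non_missing <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(x[NA_integer_])
  x[max(ok)]
}

#' Box-Cox transform and Z-score standardization
#'
#' For each analyte: applies a positivity shift `1 - min(x)` when the
#' minimum is at or below zero, estimates the Box-Cox lambda by maximizing
#' the profile log-likelihood over a grid (default -3 to 3, step 0.01),
#' transforms, and standardizes to sample mean 0 and SD 1 (denominator
#' `n - 1`, non-missing entries). Standardization is computed on the pooled
#' sample (all diagnosis groups together). Missing values stay missing.
#'
#' @param summary Subject-level table (e.g. `summarize_subjects()$summary`).
#' @param panel Biomarker panel.
#' @param lambda_grid Grid over which the profile likelihood is maximized.
#' @param lambda_fixed Optional named vector fixing lambda for some or all
#'   analytes (e.g. `c(crp = 1)` disables the transform for CRP).
#' @return A list of class `transform_model` content: `model` (tibble with
#'   per-analyte `lambda`, `shift`, `mean`, `sd`, `n`) and `scores` (the
#'   input table with analyte columns replaced by Z scores).
#' @examples
#' sim <- generate_cohort(synthetic_config(seed = 1))
#' subj <- summarize_subjects(sim$cohort)$summary
#' std <- standardize_biomarkers(subj)
#' colMeans(std$scores[default_panel()$analyte], na.rm = TRUE)
#' @export
standardize_biomarkers <- function(summary, panel = default_panel(),
                                   lambda_grid = seq(-3, 3, by = 0.01),
                                   lambda_fixed = NULL) {
  validate_panel(panel)
  analytes <- intersect(panel$analyte, names(summary))
  scores <- summary
  model <- purrr::map_dfr(analytes, function(a) {
    x <- summary[[a]]
    ok <- !is.na(x)
    if (sum(ok) < 3) {
      stop("analyte '", a, "' has fewer than 3 non-missing values",
           call. = FALSE)
    }
    if (stats::sd(x[ok]) == 0) {
      stop("analyte '", a, "' has zero variance", call. = FALSE)
    }
    shift <- if (min(x[ok]) <= 0) 1 - min(x[ok]) else 0
    xs <- x[ok] + shift
    lambda <- if (!is.null(lambda_fixed) && a %in% names(lambda_fixed)) {
      lambda_fixed[[a]]
    } else {
      estimate_boxcox_lambda(xs, lambda_grid)
    }
    tr <- boxcox_transform(xs, lambda)
    mu <- mean(tr)
    sg <- stats::sd(tr)
    if (sg == 0) stop("analyte '", a, "' degenerate after transform",
                      call. = FALSE)
    z <- rep(NA_real_, length(x))
    z[ok] <- (tr - mu) / sg
    scores[[a]] <<- z
    tibble::tibble(analyte = a, lambda = lambda, shift = shift,
                   mean = mu, sd = sg, n = sum(ok))
  })
  out <- list(model = model, scores = scores)
  class(out) <- "transform_model"
  out
}

#' @noRd
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' @noRd
estimate_boxcox_lambda <- function(x, lambda_grid = seq(-3, 3, by = 0.01)) {
  prof <- MASS::boxcox(x ~ 1, lambda = lambda_grid, plotit = FALSE)
  prof$x[which.max(prof$y)]
}

#' @export
print.transform_model <- function(x, ...) {
  cat("Box-Cox / Z-score transform model for", nrow(x$model), "analytes\n")
  print(x$model, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname standardize_biomarkers
#' @param x A `transform_model` object.
#' @param ... Unused.
#' @export
tidy.transform_model <- function(x, ...) x$model
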