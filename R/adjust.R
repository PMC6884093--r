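#' Fit per-biomarker covariate adjustment models
#'
#' For every analyte, fits a linear model of the Z score on diagnosis plus
#' candidate covariates (age, sex, race by default) and all pairwise
#' interactions among the covariates, then retains a covariate term iff its
#' type-II ANOVA p-value is below `alpha` (an interaction brings both
#' parent terms with it), and refits the reduced model. Diagnosis is always
#' kept: its effect is never removed by [residualize()]. Models are fit on
#' the pooled sample (all diagnosis groups).
#'
#' Categorical covariates are reference-coded with the largest category as
#' reference; race categories with fewer than 5 subjects are collapsed to
#' `"Other"`. Covariates that are constant on an analyte's complete cases
#' are dropped (with their interactions) before fitting.
#'
#' @param scores Subject-level table of Z scores with `diagnosis` and
#'   covariate columns (e.g. `standardize_biomarkers()$scores`).
#' @param panel Biomarker panel.
#' @param covariates Character vector of candidate covariate columns.
#' @param alpha Selection threshold on the type-II ANOVA p-value.
#' @param interactions Include pairwise covariate-by-covariate interactions
#'   as candidates.
#' @return An object of class `adjustment_model`: per-analyte reduced `lm`
#'   fits, the term-selection table, and the covariate encodings needed to
#'   reproduce the design on new data.
#' @seealso [residualize()]
#' @export
fit_adjustment <- function(scores, panel = default_panel(),
                           covariates = c("age", "sex", "race"),
                           alpha = 0.05, interactions = TRUE) {
  validate_panel(panel)
  analytes <- intersect(panel$analyte, names(scores))
  covariates <- intersect(covariates, names(scores))
  if (!"diagnosis" %in% names(scores)) {
    stop("scores must contain a 'diagnosis' column", call. = FALSE)
  }
  prep <- prepare_covariates(scores, covariates)
  data <- prep$data

  fits <- list()
  selection <- list()
  for (a in analytes) {
    d <- data
    d$.z <- scores[[a]]
    cand <- covariates[vapply(covariates, function(v) {
      cc <- !is.na(d$.z) & !is.na(d[[v]])
      length(unique(d[[v]][cc])) >= 2
    }, logical(1))]
    cand_terms <- cand
    if (interactions && length(cand) >= 2) {
      pairs <- utils::combn(cand, 2)
      cand_terms <- c(cand, apply(pairs, 2, paste, collapse = ":"))
    }
    full_rhs <- paste(c("diagnosis", cand_terms), collapse = " + ")
    full_fml <- stats::as.formula(paste(".z ~", full_rhs))
    cc <- stats::complete.cases(d[, c(".z", "diagnosis", cand)])
    full_fit <- stats::lm(full_fml, data = d[cc, , drop = FALSE])
    if (any(is.na(stats::coef(full_fit)))) {
      bad <- names(stats::coef(full_fit))[is.na(stats::coef(full_fit))][1]
      stop("rank-deficient design for analyte '", a, "' at term '", bad, "'",
           call. = FALSE)
    }
    p_req <- length(stats::coef(full_fit))
    if (sum(cc) <= p_req + 5) {
      stop("analyte '", a, "': ", sum(cc),
           " complete cases are too few for ", p_req, " parameters",
           call. = FALSE)
    }
    an <- car::Anova(full_fit, type = 2)
    pvals <- stats::setNames(an[["Pr(>F)"]], rownames(an))
    pvals <- pvals[names(pvals) %in% cand_terms]
    selected <- names(pvals)[!is.na(pvals) & pvals < alpha]
    # interactions carry both parents
    parents <- unlist(strsplit(grep(":", selected, value = TRUE), ":"))
    selected <- union(intersect(cand_terms, union(selected, parents)),
                      character(0))
    selected <- cand_terms[cand_terms %in% selected]  # stable order

    red_rhs <- paste(c("diagnosis", selected), collapse = " + ")
    red_fit <- stats::lm(stats::as.formula(paste(".z ~", red_rhs)),
                         data = d, na.action = stats::na.omit)
    fits[[a]] <- red_fit
    selection[[a]] <- tibble::tibble(
      analyte = a, term = names(pvals), p_value = unname(pvals),
      selected = names(pvals) %in% selected)
  }
  out <- list(fits = fits, selection = dplyr::bind_rows(selection),
              covariates = covariates, alpha = alpha,
              encodings = prep$encodings)
  class(out) <- "adjustment_model"
  out
}

# Reference-codes categorical covariates (largest category first) and
# collapses race strata with < 5 subjects into "Other".
#' @noRd
prepare_covariates <- function(data, covariates, encodings = NULL) {
  out <- data[, intersect(c("subject_id", "diagnosis", covariates),
                          names(data)), drop = FALSE]
  dx_levels <- if (!is.null(encodings$diagnosis)) encodings$diagnosis else {
    lev <- unique(as.character(out$diagnosis))
    if ("HD" %in% lev) c("HD", sort(setdiff(lev, "HD"))) else sort(lev)
  }
  out$diagnosis <- factor(as.character(out$diagnosis), levels = dx_levels)
  enc <- list(diagnosis = dx_levels)
  for (v in covariates) {
    x <- out[[v]]
    if (is.numeric(x)) next
    x <- as.character(x)
    if (v == "race") {
      keep <- if (!is.null(encodings$race_keep)) encodings$race_keep else {
        tab <- table(x)
        names(tab)[tab >= 5]
      }
      x[!is.na(x) & !(x %in% keep)] <- "Other"
      enc$race_keep <- keep
    }
    lev <- if (!is.null(encodings[[v]])) encodings[[v]] else
      names(sort(table(x), decreasing = TRUE))
    lev <- union(lev, unique(x[!is.na(x)]))
    out[[v]] <- factor(x, levels = lev)
    enc[[v]] <- lev
  }
  list(data = out, encodings = enc)
}

#' Remove fitted covariate effects from Z scores
#'
#' Subtracts the fitted covariate (and covariate-interaction) contributions
#' of an [fit_adjustment()] model from each analyte's Z scores, leaving the
#' intercept and diagnosis effect in place: exactly,
#' `residual = intercept + diagnosis effect + OLS error`. A subject whose
#' model-used covariate is missing gets a missing residual for that analyte;
#' analytes whose model selected no covariates pass through unchanged.
#'
#' @param scores Subject-level Z-score table (same schema used for
#'   fitting).
#' @param model An `adjustment_model`.
#' @return The input table with analyte columns replaced by adjusted
#'   residuals (a "residual matrix" in wide subject-by-analyte form).
#' @export
residualize <- function(scores, model) {
  if (!inherits(model, "adjustment_model")) {
    stop("model must be created by fit_adjustment()", call. = FALSE)
  }
  prep <- prepare_covariates(scores, model$covariates, model$encodings)
  data <- prep$data
  out <- scores
  for (a in names(model$fits)) {
    if (!a %in% names(scores)) next
    fit <- model$fits[[a]]
    tt <- stats::delete.response(stats::terms(fit))
    tl <- attr(tt, "term.labels")
    cov_idx <- which(tl != "diagnosis")
    z <- scores[[a]]
    res <- rep(NA_real_, length(z))
    if (length(cov_idx) == 0) {
      out[[a]] <- z
      next
    }
    used <- setdiff(unique(unlist(strsplit(tl[cov_idx], ":"))), "diagnosis")
    ok <- !is.na(z)
    for (v in used) ok <- ok & !is.na(data[[v]])
    d_ok <- data[ok, , drop = FALSE]
    # diagnosis enters the design too; rows with NA diagnosis can't be built
    ok[ok] <- !is.na(d_ok$diagnosis)
    d_ok <- data[ok, , drop = FALSE]
    mf <- stats::model.frame(tt, d_ok, xlev = fit$xlevels)
    mm <- stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
    asgn <- attr(mm, "assign")
    cols <- which(asgn %in% cov_idx)
    beta <- stats::coef(fit)[colnames(mm)[cols]]
    res[ok] <- z[ok] - as.numeric(mm[, cols, drop = FALSE] %*% beta)
    out[[a]] <- res
  }
  out
}

#' @export
print.adjustment_model <- function(x, ...) {
  n_sel <- sum(x$selection$selected)
  cat("Covariate adjustment models for", length(x$fits), "analytes;",
      n_sel, "covariate terms selected at alpha =", x$alpha, "\n")
  invisible(x)
}

#' @rdname fit_adjustment
#' @param x An `adjustment_model`.
#' @param ... Unused.
#' @export
tidy.adjustment_model <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(a) {
    cf <- summary(x$fits[[a]])$coefficients
    tibble::tibble(analyte = a, term = rownames(cf),
                   estimate = cf[, 1], std_error = cf[, 2],
                   statistic = cf[, 3], p_value = cf[, 4])
  })
}

#' @rdname fit_adjustment
#' @export
glance.adjustment_model <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(a) {
    s <- summary(x$fits[[a]])
    tibble::tibble(analyte = a, r_squared = s$r.squared,
                   sigma = s$sigma, n = length(s$residuals),
                   n_covariate_terms = sum(
                     x$selection$selected[x$selection$analyte == a]))
  })
}
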