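#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values within one analysis family (a thin, validated
#' wrapper over [stats::p.adjust()] with `method = "BH"`). Adjusted values
#' are capped at 1 and never smaller than the raw values; significance is
#' conventionally declared at adjusted p < 0.05.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Adds a p_adjusted column within each family, excluding undefined results
# (NA estimates) from the family size.
#' @noRd
adjust_families <- function(results) {
  results |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_adjusted = {
      pa <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p_value)
      pa[ok] <- fdr_adjust(.data$p_value[ok])
      pa
    }) |>
    dplyr::ungroup()
}

#' Compare residuals or cluster scores between diagnosis groups
#'
#' For each variable: with `method = "anova"` (the convention for
#' marker-level residuals) the group term is tested by the F-test of a
#' linear model on the grouping factor; with `method = "t"` (the convention
#' for cluster scores between two groups) an unpaired, equal-variance
#' two-sided t-test. `method = "auto"` picks the t-test when exactly two
#' groups are present. Raw p-values are BH-adjusted within the family.
#'
#' @param data Subject-level table.
#' @param vars Character vector of value columns to compare.
#' @param group Grouping column name (character values or factor).
#' @param method `"auto"`, `"t"` or `"anova"`.
#' @param family Family label for FDR adjustment.
#' @return A tibble with one row per variable: `family`, `variable`,
#'   `method`, `estimate` (difference in group means, second minus first
#'   level, for two groups), `statistic`, `n`, `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(data, vars, group = "diagnosis",
                           method = c("auto", "t", "anova"),
                           family = "group_comparison") {
  method <- match.arg(method)
  g_all <- factor(as.character(data[[group]]))
  res <- purrr::map_dfr(vars, function(v) {
    y <- data[[v]]
    ok <- !is.na(y) & !is.na(g_all)
    y <- y[ok]
    g <- droplevels(g_all[ok])
    counts <- table(g)
    if (length(counts) < 2) {
      stop("variable '", v, "': fewer than 2 groups with data (",
           paste(setdiff(levels(g_all), names(counts)), collapse = ", "),
           " entirely missing)", call. = FALSE)
    }
    if (any(counts < 2)) {
      stop("variable '", v, "': group(s) with fewer than 2 values: ",
           paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
    }
    use <- if (method == "auto") {
      if (length(counts) == 2) "t" else "anova"
    } else method
    if (use == "t") {
      if (length(counts) != 2) {
        stop("t-test requires exactly 2 groups for variable '", v, "'",
             call. = FALSE)
      }
      tt <- stats::t.test(y ~ g, var.equal = TRUE)
      est <- mean(y[g == levels(g)[2]]) - mean(y[g == levels(g)[1]])
      tibble::tibble(variable = v, method = "t-test", estimate = est,
                     statistic = unname(tt$statistic), n = length(y),
                     p_value = tt$p.value)
    } else {
      fit <- stats::lm(y ~ g)
      an <- stats::anova(fit)
      tibble::tibble(variable = v, method = "anova", estimate = NA_real_,
                     statistic = an[["F value"]][1], n = length(y),
                     p_value = an[["Pr(>F)"]][1])
    }
  })
  res <- dplyr::mutate(res, family = family, .before = 1)
  adjust_families(res)
}

#' Pairwise-complete correlations between two sets of variables
#'
#' Correlates every `x_vars` column with every `y_vars` column on
#' pairwise-complete rows: Pearson for cross-compartment cluster scores,
#' Spearman (average ranks for ties; exact permutation p for N of at most 9
#' without ties, t approximation otherwise) for right-skewed severity
#' scales. Pairs with fewer than `min_n` complete observations are flagged
#' undefined (`NA` estimate) and excluded from the FDR family.
#'
#' @param data Subject-level table containing all variables.
#' @param x_vars,y_vars Character vectors of column names.
#' @param method `"pearson"` or `"spearman"`.
#' @param family Family label for FDR adjustment.
#' @param min_n Minimum pairwise-complete N (default 3).
#' @return A tibble: `family`, `variable_1`, `variable_2`, `method`,
#'   `estimate`, `n`, `p_value`, `p_adjusted`.
#' @export
correlate <- function(data, x_vars, y_vars,
                      method = c("pearson", "spearman"),
                      family = "correlation", min_n = 3) {
  method <- match.arg(method)
  grid <- expand.grid(variable_1 = x_vars, variable_2 = y_vars,
                      stringsAsFactors = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    v1 <- grid$variable_1[i]; v2 <- grid$variable_2[i]
    x <- data[[v1]]; y <- data[[v2]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_n) {
      return(tibble::tibble(variable_1 = v1, variable_2 = v2,
                            method = method, estimate = NA_real_, n = n,
                            p_value = NA_real_))
    }
    x <- x[ok]; y <- y[ok]
    if (method == "pearson") {
      ct <- stats::cor.test(x, y, method = "pearson")
    } else {
      no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman",
                        exact = n <= 9 && no_ties))
    }
    tibble::tibble(variable_1 = v1, variable_2 = v2, method = method,
                   estimate = unname(ct$estimate), n = n,
                   p_value = ct$p.value)
  })
  res <- dplyr::mutate(res, family = family, .before = 1)
  adjust_families(res)
}
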