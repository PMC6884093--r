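#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set for [generate_cohort()]. Defaults emulate the
#' design of a natural-history MS cohort: 51 healthy donors (HD), 118
#' relapsing-remitting (RRMS) and 173 progressive (PMS = PPMS + SPMS)
#' patients, 1-6 visits per subject, latent-factor correlation structure
#' matching the frozen cluster partition, diagnosis-group shifts on an
#' inflammation scale, age/sex/race confounding, visit-level noise
#' calibrated to a target one-way ICC, right-skewed marginals induced by an
#' inverse Box-Cox transform, completely-at-random missingness, and a
#' severity score coupled to the latent CSF humoral factor.
#'
#' All effect sizes are expressed in SD units of the latent (pre-skew)
#' biomarker scale. Shifts and slopes act on the *inflammation* scale:
#' a positive shift raises positive-polarity analytes and lowers
#' negative-polarity ones (the generator applies the polarity sign after
#' summing effects).
#'
#' @param group_sizes Named integer vector of subjects per diagnosis
#'   (`HD`, `RRMS`, `PPMS`, `SPMS`).
#' @param visits_per_subject Integer vector of length 2, inclusive range of
#'   visit counts drawn uniformly per subject.
#' @param latent_clusters Tibble with columns `cluster`, `compartment`,
#'   `members` (list) and `loadings` (list, values in `[0, 1]`); every panel
#'   analyte must appear exactly once. Default: the frozen partition with
#'   loadings 0.8 (singletons load 1).
#' @param diagnosis_effects Tibble `analyte`, `group`, `shift`: inflammation-
#'   scale mean shift (SD units) for the grouped diagnosis relative to HD.
#' @param covariate_effects Tibble `analyte`, `covariate`, `slope`:
#'   inflammation-scale slope in SD units per covariate-SD; covariates are
#'   `age`, `sex_male`, `race_black`, `race_other` (standardized in-sample).
#' @param icc_target One-way intraclass correlation of the latent-scale
#'   visit values, in `(0, 1]`.
#' @param skew_lambdas Named numeric vector, inverse Box-Cox exponent per
#'   analyte (0 = lognormal); missing analytes default to 0.5.
#' @param skew_offsets Named numeric vector of positive location offsets
#'   applied on the latent scale before the inverse Box-Cox map; defaults to
#'   3 where `lambda >= 0.75` and 2 otherwise (larger offsets keep
#'   low-lambda support safe, smaller ones keep lambda identifiable).
#' @param missing_rate Per-cell biomarker missingness probability in `[0, 1)`.
#' @param severity_coupling Named numeric vector, correlation between the
#'   named latent cluster factor(s) and the latent severity predictor;
#'   sum of squares must be `<= 1`.
#' @param severity_visit_sd Visit-level noise SD of severity scores on their
#'   native 0-10 scale.
#' @param grouping Named character vector mapping diagnosis to analysis
#'   group (default merges PPMS and SPMS into PMS).
#' @param panel Biomarker panel tibble, see [default_panel()].
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
synthetic_config <- function(group_sizes = c(HD = 51L, RRMS = 118L, PPMS = 69L, SPMS = 104L),
                             visits_per_subject = c(1L, 6L),
                             latent_clusters = default_latent_clusters(),
                             diagnosis_effects = default_diagnosis_effects(),
                             covariate_effects = default_covariate_effects(),
                             icc_target = 0.85,
                             skew_lambdas = default_skew_lambdas(),
                             skew_offsets = NULL,
                             missing_rate = 0.15,
                             severity_coupling = c(csf_2 = 0.25),
                             severity_visit_sd = 0.3,
                             grouping = c(HD = "HD", RRMS = "RRMS",
                                          PPMS = "PMS", SPMS = "PMS"),
                             panel = default_panel(),
                             seed = 42L) {
  validate_panel(panel)
  cfg <- list(
    group_sizes = group_sizes,
    visits_per_subject = as.integer(visits_per_subject),
    latent_clusters = latent_clusters,
    diagnosis_effects = diagnosis_effects,
    covariate_effects = covariate_effects,
    icc_target = icc_target,
    skew_lambdas = fill_named(skew_lambdas, panel$analyte, 0.5),
    missing_rate = missing_rate,
    severity_coupling = severity_coupling,
    severity_visit_sd = severity_visit_sd,
    grouping = grouping,
    panel = panel,
    seed = as.integer(seed)
  )
  if (is.null(skew_offsets)) {
    skew_offsets <- ifelse(cfg$skew_lambdas >= 0.75, 3, 2)
    names(skew_offsets) <- names(cfg$skew_lambdas)
  }
  cfg$skew_offsets <- fill_named(skew_offsets, panel$analyte, 2)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @noRd
fill_named <- function(x, keys, default) {
  out <- stats::setNames(rep(default, length(keys)), keys)
  if (!is.null(x)) out[intersect(names(x), keys)] <- x[intersect(names(x), keys)]
  out
}

#' Default generator building blocks
#'
#' Exported so that simulation scenarios can start from the defaults and
#' modify them: the latent cluster layout (frozen partition, loadings 0.8,
#' singletons load 1), the diagnosis-group shifts, the covariate slopes and
#' the per-analyte skew exponents.
#'
#' @return `default_latent_clusters()`: a tibble `cluster`, `compartment`,
#'   `members`, `loadings`; `default_diagnosis_effects()` /
#'   `default_covariate_effects()`: effect tibbles as documented in
#'   [synthetic_config()]; `default_skew_lambdas()`: a named numeric vector.
#' @export
default_latent_clusters <- function() {
  fc <- frozen_clusters()
  fc$loadings <- lapply(fc$members, function(m) {
    if (length(m) == 1L) 1 else rep(0.8, length(m))
  })
  fc[, c("cluster", "compartment", "members", "loadings")]
}

#' @rdname default_latent_clusters
#' @export
default_diagnosis_effects <- function() {
  tibble::tribble(
    ~analyte,        ~group,  ~shift,
    "ferritin",      "RRMS",  0.45,
    "ferritin",      "PMS",   0.50,
    "transferrin",   "RRMS",  0.30,
    "transferrin",   "PMS",   0.35,
    "serum_albumin", "RRMS",  0.15,
    "serum_albumin", "PMS",   0.35,
    "wbc",           "RRMS",  0.20,
    "wbc",           "PMS",   0.30,
    "ceruloplasmin", "PMS",   0.20,
    "esr",           "PMS",   0.20,
    "chi3l1",        "RRMS",  0.50,
    "chi3l1",        "PMS",   0.65,
    "scd14",         "RRMS",  0.15,
    "scd14",         "PMS",   0.25,
    "scd163",        "RRMS",  0.15,
    "scd163",        "PMS",   0.25,
    "sbcma",         "RRMS",  0.40,
    "sbcma",         "PMS",   0.45,
    "csf_igg",       "RRMS",  0.60,
    "csf_igg",       "PMS",   0.60,
    "igg_index",     "RRMS",  0.60,
    "igg_index",     "PMS",   0.60,
    "scd27",         "RRMS",  0.70,
    "scd27",         "PMS",   0.70
  )
}

#' @rdname default_latent_clusters
#' @export
default_covariate_effects <- function() {
  tibble::tribble(
    ~analyte,      ~covariate,   ~slope,
    "esr",         "age",        0.30,
    "esr",         "sex_male",  -0.15,
    "crp",         "age",        0.20,
    "scd14",       "age",        0.25,
    "chi3l1",      "age",        0.30,
    "csf_albumin", "age",        0.25,
    "csf_albumin", "sex_male",   0.20,
    "ferritin",    "sex_male",   0.35,
    "iron",        "sex_male",   0.20,
    "wbc",         "race_black", -0.25
  )
}

#' @rdname default_latent_clusters
#' @export
default_skew_lambdas <- function() {
  c(serum_albumin = 1, ceruloplasmin = 0.5, wbc = 0.5, crp = 0, esr = 0,
    iron = 1, ferritin = 0, transferrin = 1,
    scd14 = 0.5, scd163 = 0.5, chi3l1 = 0, sbcma = 0, scd27 = 0,
    csf_albumin = 0.5, csf_igg = 0, igg_index = 0.5)
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid synthetic_config field '", field, "': ", why, call. = FALSE)
  }
  if (any(cfg$group_sizes < 0) || is.null(names(cfg$group_sizes))) {
    bad("group_sizes", "must be a named vector of non-negative counts")
  }
  if (!all(names(cfg$group_sizes) %in% names(cfg$grouping))) {
    bad("grouping", "must cover every diagnosis in group_sizes")
  }
  if (length(cfg$visits_per_subject) != 2L ||
      any(cfg$visits_per_subject < 1L) ||
      cfg$visits_per_subject[1] > cfg$visits_per_subject[2]) {
    bad("visits_per_subject", "must be an increasing range of counts >= 1")
  }
  lc <- cfg$latent_clusters
  members <- unlist(lc$members)
  if (anyDuplicated(members)) {
    bad("latent_clusters", "an analyte appears in more than one cluster")
  }
  if (!setequal(members, cfg$panel$analyte)) {
    bad("latent_clusters", "members must cover the panel exactly")
  }
  loadings <- unlist(lc$loadings)
  if (any(loadings < 0 | loadings > 1)) {
    bad("latent_clusters", "loadings must lie in [0, 1]")
  }
  if (cfg$icc_target <= 0 || cfg$icc_target > 1) {
    bad("icc_target", "must lie in (0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    bad("missing_rate", "must lie in [0, 1)")
  }
  if (length(cfg$severity_coupling) > 0) {
    if (!all(names(cfg$severity_coupling) %in% lc$cluster)) {
      bad("severity_coupling", "names must be latent cluster names")
    }
    if (sum(cfg$severity_coupling^2) > 1) {
      bad("severity_coupling", "sum of squared couplings must be <= 1")
    }
  }
  invisible(cfg)
}

# Inverse Box-Cox map used to induce right skew; support is floored so the
# result is always positive.
#' @noRd
inv_boxcox <- function(w, lambda) {
  if (lambda == 0) return(exp(w))
  pmax(lambda * w + 1, 1e-8)^(1 / lambda)
}

# Age / sex / race / severity-scale marginals per analysis group, patterned
# on a natural-history cohort table.
#' @noRd
group_demographics <- function() {
  list(
    age = tibble::tribble(
      ~group, ~mean, ~sd,
      "HD",   39.4,  14.4,
      "RRMS", 42.3,  11.5,
      "PMS",  55.3,  10.0
    ),
    sex_male_prob = c(HD = 0.510, RRMS = 0.356, PMS = 0.474),
    race_probs = list(
      HD   = c(White = 0.417, Black = 0.417, Other = 0.166),
      RRMS = c(White = 0.692, Black = 0.256, Other = 0.052),
      PMS  = c(White = 0.822, Black = 0.136, Other = 0.042)
    ),
    severity = tibble::tribble(
      ~score,  ~group, ~mean, ~sd,
      "msss",  "HD",   1.8,   1.1,
      "msss",  "RRMS", 4.2,   2.4,
      "msss",  "PMS",  6.7,   1.9,
      "armss", "HD",   1.2,   0.9,
      "armss", "RRMS", 3.8,   2.4,
      "armss", "PMS",  6.3,   2.4,
      "msdss", "HD",   1.2,   0.3,
      "msdss", "RRMS", 1.4,   0.6,
      "msdss", "PMS",  2.3,   1.1
    )
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates a long-format visit table under a latent-factor model. Each
#' analyte `j` in cluster `c` has subject-level latent signal
#' `l_j * F_c + u_j` with `F_c, u_j` standard normal and
#' `Var(u_j) = 1 - l_j^2`, plus fixed covariate and diagnosis effects and
#' visit-level Gaussian noise whose variance is solved analytically so that
#' the one-way ICC of the latent-scale values equals `icc_target`:
#' `sigma2_visit = (1 + V_fixed) * (1 - icc) / icc`, where `V_fixed` is the
#' between-subject variance of the fixed part. The polarity sign is applied,
#' a positive offset added, and the inverse Box-Cox map with analyte-specific
#' lambda induces right skew. Severity scores are affine maps of a latent
#' predictor coupled to the named CSF factors, reported at every visit.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements `cohort` (tibble, one row per subject-visit)
#'   and `truth` (list: latent `factors`, true `partition`, effect tables,
#'   skew parameters, per-analyte visit noise SD).
#' @examples
#' sim <- generate_cohort(synthetic_config(seed = 1))
#' dplyr::count(dplyr::distinct(sim$cohort, subject_id, diagnosis), diagnosis)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be created by synthetic_config()", call. = FALSE)
  }
  validate_synthetic_config(config)
  set.seed(config$seed)
  panel <- config$panel
  demo <- group_demographics()

  diagnosis <- rep(names(config$group_sizes), times = config$group_sizes)
  n <- length(diagnosis)
  if (n < 1) stop("group_sizes sum to zero subjects", call. = FALSE)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    diagnosis = diagnosis,
    group = unname(config$grouping[diagnosis])
  )

  # covariates with diagnosis-dependent marginals (confounding by design)
  age_par <- demo$age[match(subjects$group, demo$age$group), ]
  subjects$age <- round(stats::rnorm(n, age_par$mean, age_par$sd), 1)
  subjects$age <- pmax(subjects$age, 18)
  subjects$sex <- ifelse(
    stats::runif(n) < demo$sex_male_prob[subjects$group], "M", "F")
  subjects$race <- vapply(subjects$group, function(g) {
    p <- demo$race_probs[[g]]
    sample(names(p), 1L, prob = p)
  }, character(1))

  # standardized covariate design for effect application
  xmat <- cbind(
    age = as.numeric(scale(subjects$age)),
    sex_male = as.numeric(scale(as.numeric(subjects$sex == "M"))),
    race_black = as.numeric(scale(as.numeric(subjects$race == "Black"))),
    race_other = as.numeric(scale(as.numeric(subjects$race == "Other")))
  )

  # latent factors, one per cluster
  lc <- config$latent_clusters
  fmat <- matrix(stats::rnorm(n * nrow(lc)), n, nrow(lc),
                 dimnames = list(NULL, lc$cluster))

  # per-subject visit counts
  vr <- config$visits_per_subject
  k <- if (vr[1] == vr[2]) rep(vr[1], n) else
    sample(seq(vr[1], vr[2]), n, replace = TRUE)
  visit_rows <- rep(seq_len(n), times = k)
  visit_index <- sequence(k)

  cohort <- tibble::tibble(
    subject_id = subjects$subject_id[visit_rows],
    diagnosis = subjects$diagnosis[visit_rows],
    visit = visit_index,
    age = subjects$age[visit_rows],
    sex = subjects$sex[visit_rows],
    race = subjects$race[visit_rows]
  )

  analyte_cluster <- stats::setNames(
    rep(lc$cluster, lengths(lc$members)), unlist(lc$members))
  analyte_loading <- stats::setNames(unlist(lc$loadings), unlist(lc$members))
  pol <- stats::setNames(ifelse(panel$polarity == "negative", -1, 1),
                         panel$analyte)
  visit_sd <- stats::setNames(numeric(nrow(panel)), panel$analyte)

  for (a in panel$analyte) {
    l <- analyte_loading[[a]]
    fixed <- rep(0, n)
    ce <- config$covariate_effects[config$covariate_effects$analyte == a, ]
    if (nrow(ce) > 0) {
      for (i in seq_len(nrow(ce))) {
        fixed <- fixed + ce$slope[i] * xmat[, ce$covariate[i]]
      }
    }
    de <- config$diagnosis_effects[config$diagnosis_effects$analyte == a, ]
    if (nrow(de) > 0) {
      shift <- stats::setNames(de$shift, de$group)
      fixed <- fixed + ifelse(subjects$group %in% names(shift),
                              shift[subjects$group], 0)
    }
    v_fixed <- if (n > 1) stats::var(fixed) else 0
    sig2_visit <- (1 + v_fixed) * (1 - config$icc_target) / config$icc_target
    visit_sd[[a]] <- sqrt(sig2_visit)

    u <- stats::rnorm(n, sd = sqrt(max(1 - l^2, 0)))
    eta_subject <- l * fmat[, analyte_cluster[[a]]] + u + fixed
    eta_visit <- eta_subject[visit_rows] +
      stats::rnorm(length(visit_rows), sd = sqrt(sig2_visit))
    z_obs <- pol[[a]] * eta_visit
    cohort[[a]] <- inv_boxcox(z_obs + config$skew_offsets[[a]],
                              config$skew_lambdas[[a]])
  }

  # severity: latent predictor coupled to named cluster factors
  rho <- config$severity_coupling
  s_lat <- rep(0, n)
  if (length(rho) > 0) {
    for (cl in names(rho)) s_lat <- s_lat + rho[[cl]] * fmat[, cl]
  }
  s_lat <- s_lat + stats::rnorm(n, sd = sqrt(max(1 - sum(rho^2), 0)))
  sev <- demo$severity
  for (sc in severity_cols()) {
    par <- sev[sev$score == sc, ]
    m <- par$mean[match(subjects$group, par$group)]
    s <- par$sd[match(subjects$group, par$group)]
    base <- m + s * s_lat
    vals <- base[visit_rows] +
      stats::rnorm(length(visit_rows), sd = config$severity_visit_sd)
    cohort[[sc]] <- round(pmin(pmax(vals, 0), 10), 2)
  }

  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 seed = config$seed + 1L,
                                 columns = panel$analyte)
  }

  truth <- list(
    factors = tibble::as_tibble(cbind(
      tibble::tibble(subject_id = subjects$subject_id,
                     diagnosis = subjects$diagnosis,
                     group = subjects$group),
      tibble::as_tibble(fmat))),
    partition = tibble::tibble(analyte = names(analyte_cluster),
                               cluster = unname(analyte_cluster)),
    loadings = analyte_loading,
    diagnosis_effects = config$diagnosis_effects,
    covariate_effects = config$covariate_effects,
    severity_coupling = config$severity_coupling,
    skew_lambdas = config$skew_lambdas,
    skew_offsets = config$skew_offsets,
    visit_sd = visit_sd,
    icc_target = config$icc_target
  )
  list(cohort = cohort, truth = truth)
}

#' Mask biomarker cells completely at random
#'
#' Sets biomarker cells (never identifiers, diagnosis, covariates or, by
#' default, severity scores) to `NA` independently with the given
#' probability. Deterministic given the seed.
#'
#' @param cohort A visit table.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @param columns Columns eligible for masking; defaults to the panel
#'   analytes present in `cohort`.
#' @return The cohort with masked cells.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L,
                               columns = intersect(default_panel()$analyte,
                                                   names(cohort))) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)", call. = FALSE)
  }
  protected <- c("subject_id", "diagnosis", "visit", "age", "sex", "race")
  columns <- setdiff(intersect(columns, names(cohort)), protected)
  if (rate == 0 || length(columns) == 0) return(cohort)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(nrow(cohort) * length(columns)) < rate,
                 nrow(cohort), length(columns))
  for (j in seq_along(columns)) {
    cohort[[columns[j]]][mask[, j]] <- NA
  }
  cohort
}
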