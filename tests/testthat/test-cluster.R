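test_that("polarity flip negates exactly the negative APR columns", {
  sim <- generate_cohort(small_config(seed = 30))
  d <- sim$cohort
  flipped <- apply_polarity(d)
  neg <- c("serum_albumin", "iron", "transferrin")
  for (a in neg) expect_equal(flipped[[a]], -d[[a]])
  for (a in setdiff(default_panel()$analyte, neg)) {
    expect_identical(flipped[[a]], d[[a]])
  }
  # involution
  expect_identical(apply_polarity(flipped), d)
  # unknown analyte errors
  d$mystery <- 1
  expect_error(apply_polarity(d, analytes = "mystery"), "absent")
})

make_residual_cohort <- function(seed, loading = 0.8, n_groups = c(
  HD = 50L, RRMS = 100L, PPMS = 75L, SPMS = 75L)) {
  lc <- default_latent_clusters()
  lc$loadings <- lapply(lc$members, function(m) {
    if (length(m) == 1L) 1 else rep(loading, length(m))
  })
  cfg <- synthetic_config(
    group_sizes = n_groups, visits_per_subject = c(1L, 1L),
    latent_clusters = lc,
    diagnosis_effects = default_diagnosis_effects()[0, ],
    covariate_effects = default_covariate_effects()[0, ],
    icc_target = 1, missing_rate = 0, seed = seed)
  sim <- generate_cohort(cfg)
  subj <- summarize_subjects(sim$cohort)$summary
  std <- standardize_biomarkers(subj, lambda_grid = coarse_grid)
  apply_polarity(std$scores)
}

test_that("derived blood clusters recover the generating partition", {
  resid <- make_residual_cohort(seed = 31)
  defs <- derive_clusters(resid, compartment = "blood", population = "all")
  members <- lapply(defs$members, sort)
  has_group <- function(g) any(vapply(members, identical, logical(1),
                                      sort(g)))
  expect_true(has_group(c("ceruloplasmin", "crp", "esr", "iron")))
  expect_true(has_group(c("serum_albumin", "wbc")))
  expect_true(has_group(c("ferritin", "transferrin")))
  # output is a partition of the compartment
  expect_setequal(unlist(defs$members),
                  default_panel()$analyte[default_panel()$compartment ==
                                            "blood"])
  cors <- attr(defs, "correlations")
  expect_true(all(cors$n >= 10))
})

test_that("an unattainable threshold yields all singletons", {
  resid <- make_residual_cohort(seed = 32)
  defs <- derive_clusters(resid, compartment = "blood", population = "all",
                          r_threshold = 1.0)
  expect_true(all(lengths(defs$members) == 1))
  expect_equal(nrow(defs), 8)
})

test_that("too few pairwise-complete observations advise a frozen partition", {
  resid <- make_residual_cohort(seed = 33)
  resid$crp[-(1:5)] <- NA
  expect_error(derive_clusters(resid, compartment = "blood"),
               "frozen")
})

test_that("the frozen partition matches the published cluster memberships", {
  fc <- frozen_clusters()
  get <- function(nm) sort(fc$members[[which(fc$cluster == nm)]])
  expect_equal(get("blood_1"), sort(c("ceruloplasmin", "crp", "esr", "iron")))
  expect_equal(get("blood_2"), sort(c("wbc", "serum_albumin")))
  expect_equal(get("blood_3"), sort(c("ferritin", "transferrin")))
  expect_equal(get("csf_1"), sort(c("scd14", "scd163", "chi3l1")))
  expect_equal(get("csf_2"), sort(c("csf_igg", "igg_index", "sbcma")))
  expect_equal(get("scd27"), "scd27")
  expect_equal(get("csf_albumin"), "csf_albumin")
  # blood on all patients, CSF on MS only
  expect_true(all(fc$population[fc$compartment == "blood"] == "all"))
  expect_true(all(fc$population[fc$compartment == "csf"] == "ms_only"))
})

test_that("cluster scores are missing-aware means of member residuals", {
  resid <- tibble::tibble(
    subject_id = c("P1", "P2", "P3", "P4"),
    diagnosis = "RRMS",
    scd14 = c(0.5, 0.3, 1, NA),
    scd163 = c(-0.5, NA, 2, NA),
    chi3l1 = c(0, 0.9, 3, NA),
    scd27 = c(2, -1, 0.5, NA))
  defs <- frozen_clusters()[frozen_clusters()$cluster %in%
                              c("csf_1", "scd27"), ]
  sc <- score_clusters(resid, defs)
  expect_equal(sc$csf_1, c(0, 0.6, 2, NA))
  expect_equal(sc$csf_1_n, c(3, 2, 3, 0))
  # singleton score is the residual column itself
  expect_equal(sc$scd27, resid$scd27)
  # invariant to member ordering
  defs2 <- defs
  defs2$members[[which(defs2$cluster == "csf_1")]] <-
    rev(defs2$members[[which(defs2$cluster == "csf_1")]])
  expect_equal(score_clusters(resid, defs2)$csf_1, sc$csf_1)
})

test_that("score_clusters validates definitions and members", {
  resid <- tibble::tibble(subject_id = "P1", diagnosis = "HD", scd14 = 1)
  bad <- tibble::tibble(cluster = "x", compartment = "csf",
                        members = list(character(0)))
  expect_error(score_clusters(resid, bad), "empty")
  bad2 <- tibble::tibble(cluster = "x", compartment = "csf",
                         members = list("nonexistent"))
  expect_error(score_clusters(resid, bad2), "missing from")
})

test_that("with unit loadings every member correlates 1 with its score", {
  resid <- make_residual_cohort(seed = 34, loading = 1)
  defs <- frozen_clusters()[frozen_clusters()$cluster == "csf_1", ]
  sc <- score_clusters(resid, defs)
  for (m in defs$members[[1]]) {
    expect_gt(cor(resid[[m]], sc$csf_1), 0.999)
  }
})

test_that("polarity flip before or after residualization gives equal scores", {
  sim <- generate_cohort(small_config(seed = 35))
  subj <- summarize_subjects(sim$cohort)$summary
  std <- standardize_biomarkers(subj, lambda_grid = coarse_grid)
  fit_a <- fit_adjustment(std$scores)
  path_a <- apply_polarity(residualize(std$scores, fit_a))
  flipped_first <- apply_polarity(std$scores)
  fit_b <- fit_adjustment(flipped_first)
  path_b <- residualize(flipped_first, fit_b)
  for (a in default_panel()$analyte) {
    expect_lt(max(abs(path_a[[a]] - path_b[[a]]), na.rm = TRUE), 1e-10)
  }
  defs <- frozen_clusters()
  sa <- score_clusters(path_a, defs)
  sb <- score_clusters(path_b, defs)
  for (cl in defs$cluster) {
    expect_lt(max(abs(sa[[cl]] - sb[[cl]]), na.rm = TRUE), 1e-10)
  }
})
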