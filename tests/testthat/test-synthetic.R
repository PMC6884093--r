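test_that("default cohort matches the study design: 51 HD, 118 RRMS, 173 PMS", {
  sim <- generate_cohort(synthetic_config(seed = 3))
  subj <- dplyr::distinct(sim$cohort, subject_id, diagnosis)
  counts <- table(subj$diagnosis)
  expect_equal(unname(counts[["HD"]]), 51)
  expect_equal(unname(counts[["RRMS"]]), 118)
  expect_equal(unname(counts[["PPMS"]] + counts[["SPMS"]]), 173)
  # all schema columns present
  expect_true(all(c("subject_id", "diagnosis", "visit", "age", "sex", "race",
                    default_panel()$analyte, "msss", "armss", "msdss")
                  %in% names(sim$cohort)))
})

test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$factors, b$truth$factors)
  c2 <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("noiseless unit-loading clusters correlate perfectly after polarity", {
  lc <- default_latent_clusters()
  lc$loadings <- lapply(lc$members, function(m) rep(1, length(m)))
  cfg <- synthetic_config(
    group_sizes = c(HD = 40L, RRMS = 40L, PPMS = 10L, SPMS = 10L),
    visits_per_subject = c(1L, 1L),
    latent_clusters = lc,
    diagnosis_effects = default_diagnosis_effects()[0, ],
    covariate_effects = default_covariate_effects()[0, ],
    icc_target = 1,
    skew_lambdas = setNames(rep(1, 16), default_panel()$analyte),
    missing_rate = 0, seed = 11)
  sim <- generate_cohort(cfg)
  flipped <- apply_polarity(sim$cohort)
  for (i in which(lengths(lc$members) > 1)) {
    m <- lc$members[[i]]
    r <- cor(flipped[[m[1]]], flipped[[m[2]]])
    expect_equal(r, 1, tolerance = 1e-10)
  }
})

test_that("latent correlations follow the factor model: products of loadings", {
  cfg <- synthetic_config(
    group_sizes = c(HD = 250L, RRMS = 250L, PPMS = 250L, SPMS = 250L),
    visits_per_subject = c(1L, 1L),
    diagnosis_effects = default_diagnosis_effects()[0, ],
    covariate_effects = default_covariate_effects()[0, ],
    icc_target = 1,  # no visit noise: observe the subject-level latent scale
    skew_lambdas = setNames(rep(1, 16), default_panel()$analyte),
    missing_rate = 0, seed = 5)
  sim <- generate_cohort(cfg)
  d <- apply_polarity(sim$cohort)
  # same cluster: expected r = product of loadings = 0.64
  expect_equal(cor(d$ceruloplasmin, d$crp), 0.8 * 0.8, tolerance = 0.05)
  expect_equal(cor(d$scd14, d$chi3l1), 0.8 * 0.8, tolerance = 0.05)
  expect_equal(cor(d$ferritin, d$transferrin), 0.64, tolerance = 0.05)
  # different clusters, independent factors: r near 0
  expect_lt(abs(cor(d$crp, d$ferritin)), 0.1)
  expect_lt(abs(cor(d$wbc, d$scd27)), 0.1)
  expect_lt(abs(cor(d$esr, d$csf_igg)), 0.1)
})

test_that("visit noise is calibrated to the target one-way ICC", {
  for (target in c(0.5, 0.8, 0.95)) {
    cfg <- synthetic_config(
      group_sizes = c(HD = 100L, RRMS = 150L, PPMS = 125L, SPMS = 125L),
      visits_per_subject = c(4L, 4L),
      icc_target = target,
      skew_lambdas = setNames(rep(1, 16), default_panel()$analyte),
      missing_rate = 0, seed = round(100 * target))
    sim <- generate_cohort(cfg)
    for (a in c("crp", "chi3l1", "scd27")) {
      icc <- oracle_icc(sim$cohort$subject_id, sim$cohort[[a]])
      expect_equal(icc, target, tolerance = 0.05,
                   label = sprintf("ICC(%s) at target %.2f", a, target))
    }
  }
})

test_that("severity scores live on their native scale and couple to CSF factors", {
  sim <- generate_cohort(synthetic_config(seed = 21))
  expect_true(all(sim$cohort$msss >= 0 & sim$cohort$msss <= 10, na.rm = TRUE))
  expect_true(all(sim$cohort$armss >= 0 & sim$cohort$armss <= 10,
                  na.rm = TRUE))
  # severity correlates with the coupled latent factor, not with others
  subj <- dplyr::distinct(sim$cohort, subject_id, .keep_all = TRUE)
  j <- dplyr::inner_join(subj[, c("subject_id", "msss")],
                         sim$truth$factors, by = "subject_id")
  ms <- j[j$group != "HD", ]
  expect_gt(cor(ms$msss, ms$csf_2, use = "complete.obs"), 0.1)
  expect_lt(abs(cor(ms$msss, ms$blood_1, use = "complete.obs")), 0.12)
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(icc_target = 0), "icc_target")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(visits_per_subject = c(5, 2)),
               "visits_per_subject")
  lc <- default_latent_clusters()
  lc$loadings[[1]][1] <- 1.5
  expect_error(synthetic_config(latent_clusters = lc), "latent_clusters")
  expect_error(synthetic_config(severity_coupling = c(nope = 0.2)),
               "severity_coupling")
})

test_that("missingness injection is calibrated, protected and deterministic", {
  sim <- generate_cohort(small_config(seed = 2, missing_rate = 0))
  expect_identical(inject_missingness(sim$cohort, 0), sim$cohort)

  masked <- inject_missingness(sim$cohort, 0.2, seed = 9)
  cells <- as.matrix(masked[, default_panel()$analyte])
  expect_gt(length(cells), 4000)
  expect_equal(mean(is.na(cells)), 0.2, tolerance = 0.02)
  expect_false(anyNA(masked$subject_id))
  expect_false(anyNA(masked$diagnosis))
  expect_false(anyNA(masked$age))

  again <- inject_missingness(sim$cohort, 0.2, seed = 9)
  expect_identical(masked, again)
  expect_error(inject_missingness(sim$cohort, 1.2), "rate")
  expect_error(inject_missingness(sim$cohort, -0.1), "rate")
})
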