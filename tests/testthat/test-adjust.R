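test_that("a real age effect is selected and estimated; null covariates are not", {
  d <- covariate_frame(400, seed = 10)
  set.seed(11)
  d$crp <- 0.5 * as.numeric(scale(d$age)) + rnorm(400, sd = 0.8)
  fit <- fit_adjustment(d, one_analyte_panel(), interactions = FALSE)
  sel <- fit$selection
  expect_true(sel$selected[sel$term == "age"])
  expect_false(sel$selected[sel$term == "sex"])
  expect_false(sel$selected[sel$term == "race"])
  cf <- tidy(fit)
  age_slope <- unname(cf$estimate[cf$term == "age"] * sd(d$age))
  expect_equal(age_slope, 0.5, tolerance = 0.1)
})

test_that("the selection rule has the nominal type-I rate under the null", {
  hits <- logical(500)
  for (i in seq_len(500)) {
    d <- covariate_frame(120, seed = 1000 + i)
    set.seed(2000 + i)
    d$crp <- rnorm(120)
    fit <- fit_adjustment(d, one_analyte_panel(), interactions = FALSE)
    sel <- fit$selection
    hits[i] <- sel$selected[sel$term == "age"]
  }
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("constant covariates are dropped before fitting", {
  d <- covariate_frame(100, seed = 12)
  d$sex <- "F"
  set.seed(13)
  d$crp <- rnorm(100)
  fit <- fit_adjustment(d, one_analyte_panel())
  expect_false("sex" %in% fit$selection$term)
  expect_s3_class(fit$fits$crp, "lm")
})

test_that("a selected interaction always carries both parent terms", {
  d <- covariate_frame(500, seed = 14)
  set.seed(15)
  male <- as.numeric(d$sex == "M")
  d$crp <- 0.8 * as.numeric(scale(d$age)) * male + rnorm(500, sd = 0.6)
  fit <- fit_adjustment(d, one_analyte_panel())
  sel <- fit$selection[fit$selection$selected, ]
  if ("age:sex" %in% sel$term) {
    expect_true(all(c("age", "sex") %in% sel$term))
  }
  expect_true("age:sex" %in% sel$term)
})

test_that("residualize with no selected covariates returns the input", {
  d <- covariate_frame(150, seed = 16)
  set.seed(17)
  d$crp <- rnorm(150)
  fit <- fit_adjustment(d, one_analyte_panel())
  if (!any(fit$selection$selected)) {
    out <- residualize(d, fit)
    expect_identical(out$crp, d$crp)
  } else {
    succeed("covariate selected by chance; identity case not exercised")
  }
})

test_that("residuals equal intercept + diagnosis effect + OLS error exactly", {
  d <- covariate_frame(300, seed = 18)
  set.seed(19)
  d$crp <- 0.4 * as.numeric(scale(d$age)) - 0.3 * (d$sex == "M") +
    0.5 * (d$diagnosis != "HD") + rnorm(300, sd = 0.7)
  fit <- fit_adjustment(d, one_analyte_panel())
  res <- residualize(d, fit)$crp
  lmfit <- fit$fits$crp
  cf <- coef(lmfit)
  dx_part <- vapply(d$diagnosis, function(g) {
    nm <- paste0("diagnosis", g)
    if (nm %in% names(cf)) cf[[nm]] else 0
  }, numeric(1))
  expected <- cf[["(Intercept)"]] + dx_part + residuals(lmfit)
  expect_lt(max(abs(res - expected)), 1e-10)
})

test_that("OLS errors are orthogonal to every included covariate column", {
  d <- covariate_frame(300, seed = 20)
  set.seed(21)
  d$crp <- 0.4 * as.numeric(scale(d$age)) + 0.3 * (d$race == "Black") +
    rnorm(300, sd = 0.7)
  fit <- fit_adjustment(d, one_analyte_panel())
  lmfit <- fit$fits$crp
  e <- residuals(lmfit)
  X <- model.matrix(lmfit)
  dots <- abs(crossprod(X, e))
  expect_lt(max(dots), 1e-8 * length(e))
})

test_that("residualization commutes with negating the analyte column", {
  d <- covariate_frame(250, seed = 22)
  set.seed(23)
  d$crp <- 0.5 * as.numeric(scale(d$age)) + rnorm(250, sd = 0.8)
  f1 <- fit_adjustment(d, one_analyte_panel())
  r1 <- -residualize(d, f1)$crp
  d2 <- d
  d2$crp <- -d$crp
  f2 <- fit_adjustment(d2, one_analyte_panel())
  r2 <- residualize(d2, f2)$crp
  expect_lt(max(abs(r1 - r2)), 1e-12)
})

test_that("a true group shift survives adjustment", {
  # noise sd and n chosen so the sampling error of the group contrast
  # (~0.05) is well inside the asserted band
  d <- covariate_frame(800, seed = 24)
  set.seed(25)
  d$crp <- 0.4 * as.numeric(scale(d$age)) + 0.6 * (d$diagnosis != "HD") +
    rnorm(800, sd = 0.5)
  fit <- fit_adjustment(d, one_analyte_panel())
  res <- residualize(d, fit)$crp
  shift <- mean(res[d$diagnosis != "HD"]) - mean(res[d$diagnosis == "HD"])
  expect_lt(abs(shift - 0.6), 0.15)
})

test_that("missing covariates blank residuals only where the model uses them", {
  d <- covariate_frame(300, seed = 26)
  set.seed(27)
  d$crp <- 0.6 * as.numeric(scale(d$age)) + rnorm(300, sd = 0.6)
  d$esr <- rnorm(300)  # no covariate effect
  panel <- default_panel()[default_panel()$analyte %in% c("crp", "esr"), ]
  d$age[1:5] <- NA
  fit <- fit_adjustment(d, panel, interactions = FALSE)
  sel <- fit$selection
  expect_true(sel$selected[sel$analyte == "crp" & sel$term == "age"])
  res <- residualize(d, fit)
  expect_true(all(is.na(res$crp[1:5])))
  if (!any(sel$selected[sel$analyte == "esr"])) {
    expect_false(anyNA(res$esr[1:5]))
  }
})

test_that("adding a null covariate barely perturbs the residuals", {
  d <- covariate_frame(400, seed = 28)
  set.seed(29)
  d$crp <- 0.5 * as.numeric(scale(d$age)) + rnorm(400, sd = 0.8)
  f_age <- fit_adjustment(d, one_analyte_panel(), covariates = "age")
  r_age <- residualize(d, f_age)$crp
  # force sex into the model by selecting with alpha = 1
  f_both <- fit_adjustment(d, one_analyte_panel(),
                           covariates = c("age", "sex"), alpha = 1,
                           interactions = FALSE)
  r_both <- residualize(d, f_both)$crp
  expect_lt(abs(mean(r_both - r_age)), 0.05)
  expect_lt(sd(r_both - r_age), 3 / sqrt(400))
})
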