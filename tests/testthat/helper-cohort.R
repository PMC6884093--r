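# Shared fixtures and independent oracles used across test files.

# Small cohort for fast end-to-end runs.
small_config <- function(seed = 1,
                         group_sizes = c(HD = 30L, RRMS = 40L, PPMS = 20L,
                                         SPMS = 30L), ...) {
  synthetic_config(group_sizes = group_sizes, seed = seed, ...)
}

coarse_grid <- seq(-3, 3, by = 0.05)

# Independent one-way ANOVA ICC oracle built on stats::anova/lm rather than
# the package's own mean-squares code path.
oracle_icc <- function(subject, value) {
  d <- data.frame(s = factor(subject), y = value)
  an <- stats::anova(stats::lm(y ~ s, data = d))
  msb <- an$`Mean Sq`[1]
  msw <- an$`Mean Sq`[2]
  ni <- as.numeric(table(d$s))
  n <- sum(ni)
  a <- length(ni)
  k0 <- (n - sum(ni^2) / n) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

# Brute-force Benjamini-Hochberg step-up: adjusted p(i) = min over j >= i of
# p(j) * m / j (on the sorted scale), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Inverse Box-Cox used to build skewed draws independently of the package.
oracle_inv_boxcox <- function(w, lambda) {
  if (lambda == 0) exp(w) else pmax(lambda * w + 1, 1e-8)^(1 / lambda)
}

# One-analyte panel for transform-level tests.
one_analyte_panel <- function(name = "crp") {
  tibble::tibble(analyte = name, compartment = "blood",
                 polarity = "positive", units = "")
}

# Subject-level table with a known z column and covariates, for adjustment
# tests that need a direct (non-generator) oracle.
covariate_frame <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    diagnosis = sample(c("HD", "RRMS", "PMS"), n, replace = TRUE),
    age = rnorm(n, 50, 12),
    sex = sample(c("F", "M"), n, replace = TRUE),
    race = sample(c("White", "Black", "Other"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  )
}
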