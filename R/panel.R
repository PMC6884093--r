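#' Default blood and CSF biomarker panel
#'
#' Metadata for the 16-analyte inflammation panel: eight blood acute phase
#' reactants (APRs) and eight cerebrospinal-fluid (CSF) immune analytes.
#' The `polarity` column records whether an analyte rises (`"positive"`) or
#' falls (`"negative"`) during inflammation; negative APRs (serum albumin,
#' iron, transferrin) are multiplied by -1 before clustering so that all
#' expected within-cluster correlations are positive.
#'
#' @return A tibble with columns `analyte`, `compartment` (`"blood"` or
#'   `"csf"`), `polarity` (`"positive"` or `"negative"`) and `units`.
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  tibble::tribble(
    ~analyte,        ~compartment, ~polarity,  ~units,
    "serum_albumin", "blood",      "negative", "g/dL",
    "ceruloplasmin", "blood",      "positive", "mg/dL",
    "wbc",           "blood",      "positive", "cells/uL",
    "crp",           "blood",      "positive", "mg/L",
    "esr",           "blood",      "positive", "mm/h",
    "iron",          "blood",      "negative", "mcg/dL",
    "ferritin",      "blood",      "positive", "mcg/L",
    "transferrin",   "blood",      "negative", "mg/dL",
    "scd14",         "csf",        "positive", "ng/mL",
    "scd163",        "csf",        "positive", "ng/mL",
    "chi3l1",        "csf",        "positive", "ng/mL",
    "sbcma",         "csf",        "positive", "pg/mL",
    "scd27",         "csf",        "positive", "U/mL",
    "csf_albumin",   "csf",        "positive", "mg/dL",
    "csf_igg",       "csf",        "positive", "mg/dL",
    "igg_index",     "csf",        "positive", "ratio"
  )
}

#' Frozen (published-style) biomarker cluster definitions
#'
#' The reference partition of the default panel into composite clusters:
#' three blood clusters, a CSF innate-immunity (myeloid) cluster, a CSF
#' humoral-immunity cluster, and the standalone analytes sCD27 and CSF
#' albumin. This partition is the reproduction default of the pipeline;
#' data-driven derivation via [derive_clusters()] is opt-in.
#'
#' @return A tibble with one row per cluster: `cluster`, `compartment`,
#'   `members` (list-column of analyte names), `derivation` (`"frozen"`)
#'   and `population` (`"all"` for blood, `"ms_only"` for CSF).
#' @examples
#' frozen_clusters()
#' @export
frozen_clusters <- function() {
  tibble::tibble(
    cluster = c("blood_1", "blood_2", "blood_3",
                "csf_1", "csf_2", "scd27", "csf_albumin"),
    compartment = c("blood", "blood", "blood", "csf", "csf", "csf", "csf"),
    members = list(
      c("ceruloplasmin", "crp", "esr", "iron"),
      c("wbc", "serum_albumin"),
      c("ferritin", "transferrin"),
      c("scd14", "scd163", "chi3l1"),
      c("csf_igg", "igg_index", "sbcma"),
      "scd27",
      "csf_albumin"
    ),
    derivation = "frozen",
    population = c(rep("all", 3), rep("ms_only", 4))
  )
}

#' @noRd
validate_panel <- function(panel) {
  req <- c("analyte", "compartment", "polarity")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$analyte)) {
    stop("panel analyte names must be unique", call. = FALSE)
  }
  if (!all(panel$compartment %in% c("blood", "csf"))) {
    stop("panel compartment must be 'blood' or 'csf'", call. = FALSE)
  }
  if (!all(panel$polarity %in% c("positive", "negative"))) {
    stop("panel polarity must be 'positive' or 'negative'", call. = FALSE)
  }
  invisible(panel)
}

# Severity scale columns consumed (never computed) by the pipeline.
severity_cols <- function() c("msss", "armss", "msdss")
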