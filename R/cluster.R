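#' Flip the polarity of negative acute phase reactants
#'
#' Multiplies the columns of negative-polarity analytes (serum albumin,
#' iron, transferrin in the default panel) by -1 so that all analytes point
#' in the "more inflammation = higher" direction before clustering. The
#' operation is an involution and, because the adjustment model is linear,
#' commutes with [residualize()] up to floating-point error.
#'
#' @param residuals Subject-by-analyte table of residuals (or Z scores).
#' @param panel Biomarker panel defining polarity for every analyte present.
#' @param analytes Columns to consider; defaults to panel analytes present.
#' @return The table with negative-polarity columns negated.
#' @export
apply_polarity <- function(residuals, panel = default_panel(),
                           analytes = intersect(panel$analyte,
                                                names(residuals))) {
  validate_panel(panel)
  absent <- setdiff(analytes, panel$analyte)
  if (length(absent) > 0) {
    stop("analyte(s) absent from panel: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  neg <- panel$analyte[panel$polarity == "negative"]
  for (a in intersect(neg, analytes)) {
    residuals[[a]] <- -residuals[[a]]
  }
  residuals
}

#' Derive biomarker clusters from the residual correlation structure
#'
#' Builds a graph on the analytes of one compartment with an edge wherever
#' the pairwise-complete Pearson correlation of the (post-polarity)
#' residuals is at least `r_threshold` with raw p < 0.05; clusters are the
#' connected components, ordered by size then name. Blood clusters are
#' conventionally derived on all patients and CSF clusters on MS patients
#' only (`population = "ms_only"`).
#'
#' @param residuals Subject-by-analyte residual table including a
#'   `diagnosis` column.
#' @param panel Biomarker panel.
#' @param compartment `"blood"` or `"csf"`.
#' @param population `"all"` or `"ms_only"` (drops `diagnosis == "HD"`).
#' @param r_threshold Minimum Pearson r for an edge (default 0.3).
#' @param min_pairs Minimum pairwise-complete n per pair; below it the
#'   derivation errors and a frozen partition should be used instead.
#' @return A cluster-definition tibble (same shape as [frozen_clusters()])
#'   with attribute `"correlations"` holding the pairwise r/p/n table.
#' @export
derive_clusters <- function(residuals, panel = default_panel(),
                            compartment = c("blood", "csf"),
                            population = c("all", "ms_only"),
                            r_threshold = 0.3, min_pairs = 10) {
  compartment <- match.arg(compartment)
  population <- match.arg(population)
  validate_panel(panel)
  analytes <- intersect(panel$analyte[panel$compartment == compartment],
                        names(residuals))
  if (length(analytes) < 2) {
    stop("need at least 2 analytes in compartment '", compartment, "'",
         call. = FALSE)
  }
  d <- residuals
  if (population == "ms_only") d <- d[d$diagnosis != "HD", , drop = FALSE]

  pairs <- utils::combn(sort(analytes), 2)
  cors <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a1 <- pairs[1, i]; a2 <- pairs[2, i]
    ok <- !is.na(d[[a1]]) & !is.na(d[[a2]])
    n <- sum(ok)
    if (n < min_pairs) {
      stop("pair (", a1, ", ", a2, ") has only ", n,
           " pairwise-complete observations (< ", min_pairs,
           "); use the frozen partition instead", call. = FALSE)
    }
    ct <- stats::cor.test(d[[a1]][ok], d[[a2]][ok])
    tibble::tibble(analyte_1 = a1, analyte_2 = a2,
                   r = unname(ct$estimate), p_value = ct$p.value, n = n)
  })

  edges <- cors[cors$r >= r_threshold & cors$p_value < 0.05, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("analyte_1", "analyte_2")], directed = FALSE,
    vertices = sort(analytes))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]

  defs <- tibble::tibble(
    cluster = paste0(compartment, "_", seq_along(groups)),
    compartment = compartment,
    members = unname(groups),
    derivation = "data-driven",
    population = population
  )
  # singletons keep their analyte name, as in the frozen layout
  single <- lengths(defs$members) == 1
  defs$cluster[single] <- unlist(defs$members[single])
  defs$cluster[!single] <- paste0(compartment, "_", seq_len(sum(!single)))
  attr(defs, "correlations") <- cors
  defs
}

#' Per-patient cluster scores
#'
#' Averages the non-missing member residuals of each cluster per subject; a
#' score is missing only when every member is missing, and the number of
#' contributing members is recorded alongside.
#'
#' @param residuals Subject-by-analyte residual table (post-polarity).
#' @param definitions Cluster-definition tibble ([frozen_clusters()] or
#'   [derive_clusters()] output, possibly row-bound across compartments).
#' @return A tibble with `subject_id`, `diagnosis` (if present), one score
#'   column per cluster and one `<cluster>_n` member-count column.
#' @export
score_clusters <- function(residuals, definitions) {
  if (any(lengths(definitions$members) == 0)) {
    stop("empty cluster definition", call. = FALSE)
  }
  absent <- setdiff(unlist(definitions$members), names(residuals))
  if (length(absent) > 0) {
    stop("member analyte(s) missing from residual table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c("subject_id", "diagnosis"), names(residuals))
  out <- residuals[, keep, drop = FALSE]
  for (i in seq_len(nrow(definitions))) {
    m <- as.matrix(residuals[, definitions$members[[i]], drop = FALSE])
    cnt <- rowSums(!is.na(m))
    score <- rowMeans(m, na.rm = TRUE)
    score[cnt == 0] <- NA_real_
    nm <- definitions$cluster[i]
    out[[nm]] <- score
    out[[paste0(nm, "_n")]] <- cnt
  }
  tibble::as_tibble(out)
}
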