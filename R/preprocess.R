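#' Label samples under the A/T biomarker framework
#'
#' Applies the amyloid/tau classification used to define biologically
#' confirmed cases and controls: a sample is a case (`"AD"`) when CSF
#' Abeta42 falls below the amyloid cutoff, regardless of cognitive status; a
#' control when it is cognitively normal with Abeta42 at or above the cutoff
#' and p-tau181 at or below the tau cutoff; anything else is `"excluded"`.
#' Cutoffs are cohort-specific parameters (e.g. 1098/26.64 pg/ml for the
#' ADNI-style discovery setting) and are never hard-coded.
#'
#' @param records data frame with at least `sample_id`, `diagnosis`
#'   (`CN`/`MCI`/`dementia`), `abeta42`, `ptau181`.
#' @param abeta_cutoff,ptau_cutoff positive cutoffs in pg/ml.
#' @return `records` with columns `at_label` (`AD`/`control`/`excluded`) and
#'   `at_reason` (why a record was excluded; `NA` otherwise). Records with a
#'   missing biomarker are flagged excluded, not dropped.
#' @export
classify_at_framework <- function(records, abeta_cutoff, ptau_cutoff) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "diagnosis", "abeta42", "ptau181")
  if (!all(need %in% names(records)))
    stop("`records` needs columns: ", paste(need, collapse = ", "))
  if (abeta_cutoff <= 0 || ptau_cutoff <= 0)
    stop("cutoffs must be positive")
  lab <- rep("excluded", nrow(records))
  reason <- rep(NA_character_, nrow(records))
  miss <- is.na(records$abeta42) | is.na(records$ptau181)
  reason[miss] <- "missing biomarker"
  is_ad <- !is.na(records$abeta42) & records$abeta42 < abeta_cutoff
  lab[is_ad] <- "AD"
  is_ctrl <- !miss & records$diagnosis == "CN" &
    records$abeta42 >= abeta_cutoff & records$ptau181 <= ptau_cutoff
  lab[is_ctrl] <- "control"
  reason[lab == "excluded" & !miss] <- "amyloid-negative non-control"
  records$at_label <- lab
  records$at_reason <- reason
  records
}

#' Remove analytes with excessive missingness
#'
#' Drops every analyte whose missing fraction is strictly greater than
#' `max_missing_rate` (an analyte at exactly the cutoff is kept).
#'
#' @param matrix a raw-scale [proteomic_matrix()].
#' @param max_missing_rate maximum tolerated missing fraction (default 0.10).
#' @return The filtered matrix, with attribute `"removed"` listing the
#'   excluded analyte ids and their missing fractions.
#' @export
filter_missingness <- function(matrix, max_missing_rate = 0.10) {
  stopifnot(inherits(matrix, "proteomic_matrix"))
  if (matrix$scale_state != "raw")
    stop("missingness filtering expects a raw-scale matrix")
  frac <- colMeans(is.na(matrix$values))
  drop <- frac > max_missing_rate
  if (all(drop)) stop("all analytes exceed the missingness cutoff")
  out <- matrix[, !drop]
  attr(out, "removed") <- data.frame(analyte_id = colnames(matrix$values)[drop],
                                     missing_fraction = unname(frac[drop]),
                                     stringsAsFactors = FALSE)
  out
}

#' Collapse multiple aptamers per protein to the most discriminating one
#'
#' Where several aptamers target one protein, keeps the single aptamer with
#' the largest absolute difference in mean log2 abundance between two
#' reference groups (typically biomarker-negative controls vs biologically
#' defined cases). Exact ties resolve to the lexicographically first analyte
#' id, for determinism.
#'
#' @param matrix a raw-scale [proteomic_matrix()] with an analyte map.
#' @param group_a_ids,group_b_ids disjoint, non-empty sample id sets.
#' @return A [proteomic_matrix()] with one column per protein (columns renamed
#'   to protein ids), still raw scale.
#' @export
collapse_aptamers <- function(matrix, group_a_ids, group_b_ids) {
  stopifnot(inherits(matrix, "proteomic_matrix"))
  if (matrix$scale_state != "raw")
    stop("aptamer collapse expects a raw-scale matrix")
  if (length(group_a_ids) == 0 || length(group_b_ids) == 0)
    stop("both reference groups must be non-empty")
  if (length(intersect(group_a_ids, group_b_ids)) > 0)
    stop("reference groups must be disjoint")
  v <- log2(matrix$values)
  a <- v[rownames(v) %in% group_a_ids, , drop = FALSE]
  b <- v[rownames(v) %in% group_b_ids, , drop = FALSE]
  delta <- abs(colMeans(a, na.rm = TRUE) - colMeans(b, na.rm = TRUE))
  map <- matrix$analyte_map
  keep <- character(0)
  for (prot in unique(map$protein_id)) {
    ids <- sort(map$analyte_id[map$protein_id == prot])
    d <- delta[ids]
    if (all(is.na(d)))
      stop("protein with no complete aptamer in a reference group: ", prot)
    keep <- c(keep, ids[which.max(d)])   # which.max: first max wins ties
  }
  out <- matrix[, keep]
  pm <- out$analyte_map
  colnames(out$values) <- pm$protein_id[match(colnames(out$values),
                                              pm$analyte_id)]
  pm$analyte_id <- pm$protein_id
  out$analyte_map <- pm
  out
}

#' Log2-transform and z-score against a reference group
#'
#' Log2-transforms raw abundances, imputes residual missing entries with the
#' per-protein cohort median (on the log2 scale), then standardizes each
#' protein by the mean and standard deviation of the reference samples.
#' Positive values indicate higher-than-reference abundance. With
#' `reference_ids = NULL` the whole cohort is the reference (the convention
#' used before classifier transfer); passing the control ids gives
#' control-referenced z-scores.
#'
#' @param matrix a raw-scale [proteomic_matrix()].
#' @param reference_ids sample ids of the reference group, or `NULL` for all
#'   samples. At least two non-missing reference values per protein required.
#' @return The matrix with `scale_state = "zscore"`.
#' @export
normalize_to_controls <- function(matrix, reference_ids = NULL) {
  stopifnot(inherits(matrix, "proteomic_matrix"))
  if (matrix$scale_state != "raw")
    stop("z-scoring expects a raw-scale matrix")
  v <- log2(matrix$values)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(v))) v[is.na(v[, j]), j] <- med[j]
  if (is.null(reference_ids)) reference_ids <- rownames(v)
  ref <- v[rownames(v) %in% reference_ids, , drop = FALSE]
  if (nrow(ref) < 2) stop("need at least two reference samples")
  mu <- colMeans(ref)
  sd <- apply(ref, 2, stats::sd)
  if (any(sd == 0))
    stop("zero reference SD for protein(s): ",
         paste(colnames(v)[sd == 0], collapse = ", "))
  v <- sweep(sweep(v, 2, mu), 2, sd, `/`)
  out <- matrix
  out$values <- v
  .advance_state(.advance_state(out, "log2"), "zscore")
}

#' Read a proteomics CSV (samples as rows, analyte-id header)
#'
#' @param path CSV path; first column must be `sample_id`, remaining columns
#'   numeric analyte values with `NA` for missing.
#' @param analyte_map optional analyte-map data frame or CSV path with columns
#'   `analyte_id`, `protein_id`, `gene_symbol`.
#' @param scale_state state of the stored values (default `"raw"`).
#' @return A [proteomic_matrix()].
#' @export
read_proteomics_csv <- function(path, analyte_map = NULL,
                                scale_state = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be `sample_id`")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  if (is.character(analyte_map))
    analyte_map <- utils::read.csv(analyte_map, stringsAsFactors = FALSE)
  proteomic_matrix(v, scale_state = scale_state, analyte_map = analyte_map)
}
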