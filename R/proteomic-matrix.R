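#' Proteomic abundance matrix
#'
#' Light container for a samples-by-analytes abundance table together with its
#' processing state and the analyte-to-protein/gene map. The `scale_state`
#' records where the matrix sits in the processing chain and may only move
#' forward: `"raw"` (relative fluorescence units, strictly positive) ->
#' `"log2"` -> `"zscore"` (control- or cohort-referenced standard scores) ->
#' `"unit_interval"` (per-protein 0-1 scaling used for factorization).
#'
#' @param values numeric matrix, samples in rows, analytes in columns; both
#'   dimensions must be named with unique identifiers. `NA` marks missing
#'   measurements.
#' @param scale_state one of `"raw"`, `"log2"`, `"zscore"`, `"unit_interval"`.
#' @param analyte_map data frame with columns `analyte_id`, `protein_id`,
#'   `gene_symbol`, one row per analyte column of `values` (extra rows are
#'   dropped). `NULL` builds an identity map (analyte = protein = gene).
#'
#' @return An object of class `proteomic_matrix`.
#' @export
proteomic_matrix <- function(values, scale_state = "raw", analyte_map = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x analytes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and analyte column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate analyte ids in `values`")
  scale_state <- match.arg(scale_state,
                           c("raw", "log2", "zscore", "unit_interval"))
  if (scale_state == "raw" && any(values <= 0, na.rm = TRUE))
    stop("raw-scale values must be strictly positive")
  if (is.null(analyte_map)) {
    analyte_map <- data.frame(analyte_id = colnames(values),
                              protein_id = colnames(values),
                              gene_symbol = colnames(values),
                              stringsAsFactors = FALSE)
  }
  req <- c("analyte_id", "protein_id", "gene_symbol")
  if (!all(req %in% names(analyte_map)))
    stop("`analyte_map` needs columns: ", paste(req, collapse = ", "))
  analyte_map <- analyte_map[match(colnames(values), analyte_map$analyte_id),
                             req, drop = FALSE]
  if (anyNA(analyte_map$analyte_id))
    stop("`analyte_map` is missing entries for some analytes")
  rownames(analyte_map) <- NULL
  structure(list(values = values, scale_state = scale_state,
                 analyte_map = analyte_map),
            class = "proteomic_matrix")
}

#' @export
dim.proteomic_matrix <- function(x) dim(x$values)

#' @export
dimnames.proteomic_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.proteomic_matrix <- function(x, ...) x$values

#' Subset a proteomic matrix
#'
#' @param x a [proteomic_matrix()].
#' @param i,j sample / analyte indices (any form `[` accepts).
#' @param ... ignored.
#' @export
`[.proteomic_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  proteomic_matrix(v, scale_state = x$scale_state,
                   analyte_map = x$analyte_map[x$analyte_map$analyte_id %in%
                                                 colnames(v), , drop = FALSE])
}

#' @export
print.proteomic_matrix <- function(x, ...) {
  cat(sprintf("<proteomic_matrix> %d samples x %d analytes [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_state))
  miss <- mean(is.na(x$values))
  cat(sprintf("  %d unique proteins; %.1f%% missing\n",
              length(unique(x$analyte_map$protein_id)), 100 * miss))
  invisible(x)
}

# internal: forward-only scale transitions
.advance_state <- function(x, to) {
  order <- c(raw = 1L, log2 = 2L, zscore = 3L, unit_interval = 4L)
  if (order[[to]] <= order[[x$scale_state]])
    stop(sprintf("cannot move scale_state from '%s' to '%s'",
                 x$scale_state, to))
  x$scale_state <- to
  x
}
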