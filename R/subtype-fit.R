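#' Fit CSF proteomic subtypes
#'
#' The central fit of the package: starting from a z-scored protein matrix
#' and A/T-labelled sample records, it (1) screens for case-associated
#' proteins by Kruskal-Wallis at `alpha`, (2) rescales the selected proteins
#' to the unit interval over the cases, (3) runs multi-restart KL-NMF
#' consensus clustering over `k_range` and picks the rank where cophenetic
#' correlation, silhouette consensus and RSS drop agree, and (4) assigns
#' each case a renumbered subtype label (see [assign_subtypes()]).
#'
#' @param zmatrix a z-scored [proteomic_matrix()] over cases and controls.
#' @param records sample metadata with `sample_id`, `at_label`
#'   (`"AD"`/`"control"`/`"excluded"`), and ideally `ptau181` (drives the
#'   subtype numbering convention).
#' @param alpha Kruskal-Wallis screening threshold (default 0.01).
#' @param k_range candidate ranks (default `2:10`); ignored when `rank` is
#'   given.
#' @param rank optional fixed rank, skipping rank selection.
#' @param n_runs NMF restarts per rank (default 30).
#' @param seed integer seed controlling every restart.
#' @param max_iter,tol per-run NMF stopping parameters.
#' @return An object of class `csf_subtype` with components `selected_proteins`,
#'   `rank_selection` (NULL when `rank` was fixed), `consensus`
#'   (the `consensus_result` at the chosen rank), `subtypes` (data frame
#'   `sample_id`, `subtype`), `case_z` (the case-restricted z-matrix on the
#'   selected panel, kept for classifier transfer), and the call parameters.
#' @seealso [predict.csf_subtype()] for replication-cohort transfer.
#' @export
csf_subtype <- function(zmatrix, records, alpha = 0.01, k_range = 2:10,
                        rank = NULL, n_runs = 30L, seed = 1L,
                        max_iter = 150L, tol = 1e-4) {
  stopifnot(inherits(zmatrix, "proteomic_matrix"), is.data.frame(records))
  if (!all(c("sample_id", "at_label") %in% names(records)))
    stop("`records` needs `sample_id` and `at_label` columns")
  labels <- stats::setNames(records$at_label, records$sample_id)
  proteins <- select_ad_proteins(zmatrix, labels, alpha = alpha)
  if (length(proteins) < 2)
    stop("fewer than 2 proteins pass the Kruskal-Wallis screen")
  case_ids <- records$sample_id[records$at_label == "AD"]
  case_z <- zmatrix[rownames(zmatrix$values) %in% case_ids, proteins]
  unit <- minmax_scale(case_z)
  X <- t(unit$values)                       # proteins x cases
  if (is.null(rank)) {
    rs <- select_rank(X, k_range = k_range, n_runs = n_runs, seed = seed,
                      max_iter = max_iter, tol = tol)
    consensus <- rs$results[[as.character(rs$chosen_rank)]]
    chosen <- rs$chosen_rank
  } else {
    rs <- NULL
    consensus <- consensus_cluster(X, rank, n_runs = n_runs,
                                   seed = seed + 1000L * rank,
                                   max_iter = max_iter, tol = tol)
    chosen <- as.integer(rank)
  }
  subtypes <- assign_subtypes(consensus, records)
  structure(list(selected_proteins = proteins, rank_selection = rs,
                 consensus = consensus, chosen_rank = chosen,
                 subtypes = subtypes, case_z = case_z,
                 alpha = alpha, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "csf_subtype")
}

#' @export
print.csf_subtype <- function(x, ...) {
  cat(sprintf("<csf_subtype> %d proteins screened in, rank %d\n",
              length(x$selected_proteins), x$chosen_rank))
  cat(sprintf("  cophenetic %.3f, silhouette %.3f, RSS %.4g\n",
              x$consensus$cophenetic, x$consensus$silhouette_consensus,
              x$consensus$rss))
  cat("  subtype sizes:",
      paste(table(x$subtypes$subtype), collapse = "/"), "\n")
  invisible(x)
}

#' @export
summary.csf_subtype <- function(object, ...) {
  out <- list(chosen_rank = object$chosen_rank,
              n_selected = length(object$selected_proteins),
              sizes = table(object$subtypes$subtype),
              metrics = if (!is.null(object$rank_selection))
                object$rank_selection$metrics else NULL,
              cophenetic = object$consensus$cophenetic,
              silhouette = object$consensus$silhouette_consensus,
              rss = object$consensus$rss)
  class(out) <- "summary.csf_subtype"
  out
}

#' @export
print.summary.csf_subtype <- function(x, ...) {
  cat(sprintf("CSF proteomic subtyping: %d selected proteins, chosen rank %d\n",
              x$n_selected, x$chosen_rank))
  cat("Subtype sizes:\n"); print(x$sizes)
  if (!is.null(x$metrics)) {
    cat("Rank-selection metrics:\n"); print(x$metrics, digits = 4)
  } else {
    cat(sprintf("cophenetic %.3f, silhouette %.3f, RSS %.4g\n",
                x$cophenetic, x$silhouette, x$rss))
  }
  invisible(x)
}

#' @export
coef.csf_subtype <- function(object, ...) object$consensus$best_run$W

#' Plot rank-selection metrics of a subtype fit
#'
#' Draws cophenetic correlation, silhouette consensus and RSS drop against
#' the candidate rank; the chosen rank is marked. With `which = "consensus"`
#' draws the consensus matrix at the chosen rank, samples ordered by the
#' consensus tree.
#'
#' @param x a `csf_subtype` fit.
#' @param which `"metrics"` (default) or `"consensus"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.csf_subtype <- function(x, which = c("metrics", "consensus"), ...) {
  which <- match.arg(which)
  if (which == "metrics") {
    if (is.null(x$rank_selection)) stop("fit used a fixed rank; no metrics")
    m <- x$rank_selection$metrics
    op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
    graphics::plot(m$k, m$cophenetic, type = "b", xlab = "rank k",
                   ylab = "cophenetic correlation", ...)
    graphics::abline(v = x$chosen_rank, lty = 2)
    graphics::plot(m$k, m$silhouette, type = "b", xlab = "rank k",
                   ylab = "silhouette consensus", ...)
    graphics::abline(v = x$chosen_rank, lty = 2)
    graphics::plot(m$k, m$rss_drop, type = "b", xlab = "rank k",
                   ylab = "RSS drop", ...)
    graphics::abline(v = x$chosen_rank, lty = 2)
  } else {
    ord <- x$consensus$hclust$order
    graphics::image(x$consensus$consensus[ord, ord], axes = FALSE,
                    main = sprintf("consensus, k = %d", x$chosen_rank), ...)
  }
  invisible(x)
}
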