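#' Select disease-associated proteins by Kruskal-Wallis screening
#'
#' Retains the proteins whose distribution differs between the case and
#' control groups at `p < alpha` by the Kruskal-Wallis rank test, with no
#' multiple-comparison correction (the screen feeds an unsupervised
#' clustering step, not inference). A protein constant across all samples
#' carries no rank information and is dropped (statistic 0, p = 1).
#'
#' @param zmatrix a z-scored [proteomic_matrix()].
#' @param labels character vector aligned with the rows of `zmatrix` (or
#'   named by sample id) with values `"AD"` / `"control"`; other values are
#'   ignored.
#' @param alpha retention threshold on the unadjusted p-value (default 0.01).
#' @return Character vector of retained protein ids, in matrix column order,
#'   with the per-protein p-values as attribute `"p"`.
#' @export
select_ad_proteins <- function(zmatrix, labels, alpha = 0.01) {
  stopifnot(inherits(zmatrix, "proteomic_matrix"))
  if (zmatrix$scale_state != "zscore")
    stop("protein selection expects a z-scored matrix")
  if (!is.null(names(labels)))
    labels <- labels[rownames(zmatrix$values)]
  keep_rows <- labels %in% c("AD", "control")
  g <- factor(labels[keep_rows], levels = c("control", "AD"))
  if (any(table(g) == 0)) stop("both AD and control groups must be non-empty")
  v <- zmatrix$values[keep_rows, , drop = FALSE]
  p <- apply(v, 2, function(x) {
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) return(1)           # constant: H = 0
    stats::kruskal.test(x[ok], g[ok])$p.value
  })
  structure(colnames(v)[p < alpha], p = p)
}

#' Scale selected proteins to the unit interval
#'
#' Maps each protein to `(x - min) / (max - min)` so all values lie in
#' `[0, 1]`, the non-negative representation factorization requires. A
#' constant protein maps to all zeros. The transform is invariant to affine
#' rescaling of the input.
#'
#' @param zmatrix a z-scored [proteomic_matrix()], typically restricted to
#'   the cases and the selected proteins.
#' @param proteins optional protein ids to restrict to (default: all).
#' @return A [proteomic_matrix()] with `scale_state = "unit_interval"`.
#' @export
minmax_scale <- function(zmatrix, proteins = NULL) {
  stopifnot(inherits(zmatrix, "proteomic_matrix"))
  if (zmatrix$scale_state != "zscore")
    stop("unit-interval scaling expects a z-scored matrix")
  if (!is.null(proteins)) zmatrix <- zmatrix[, proteins]
  if (ncol(zmatrix$values) < 2) stop("need at least 2 proteins")
  v <- zmatrix$values
  rng <- apply(v, 2, range, na.rm = TRUE)
  span <- rng[2, ] - rng[1, ]
  v <- sweep(v, 2, rng[1, ])
  nz <- span > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, span[nz], `/`)
  v[, !nz] <- 0
  out <- zmatrix
  out$values <- v
  .advance_state(out, "unit_interval")
}

#' Consensus clustering over repeated NMF runs
#'
#' Runs the factorization `n_runs` times from distinct seeds
#' (`seed + 1 .. seed + n_runs`), labels samples by their dominant
#' coefficient each run, and averages the binary co-clustering
#' (connectivity) matrices into a consensus matrix. Cluster stability is
#' summarized by (i) the cophenetic correlation between the consensus
#' dissimilarity `1 - consensus` and the cophenetic distances of its
#' average-linkage hierarchy, (ii) the mean silhouette width of the
#' final labels under that dissimilarity, and (iii) the squared Frobenius
#' residual (RSS) of the best-objective run. Final labels are the k-group
#' cut of the consensus tree.
#'
#' @inheritParams nmf_factorize
#' @param n_runs number of factorization restarts (>= 2).
#' @param seed base seed; run `r` uses `seed + r`.
#' @return An object of class `consensus_result`: `rank`, `consensus`,
#'   `cophenetic`, `rss`, `silhouette_consensus`, `best_run`
#'   (an `nmf_factors`), `labels`, `run_labels` (runs x samples matrix).
#' @export
consensus_cluster <- function(X, k, n_runs = 30L, seed = 1L, max_iter = 150L,
                              tol = 1e-4) {
  if (inherits(X, "proteomic_matrix")) X <- t(X$values)
  if (n_runs < 2) stop("consensus requires n_runs >= 2")
  m <- ncol(X)
  if (k > m) stop("rank k exceeds the number of samples")
  consensus <- matrix(0, m, m, dimnames = list(colnames(X), colnames(X)))
  best <- NULL
  best_obj <- Inf
  run_labels <- matrix(NA_integer_, n_runs, m,
                       dimnames = list(NULL, colnames(X)))
  for (r in seq_len(n_runs)) {
    fit <- suppressWarnings(
      nmf_factorize(X, k, seed = seed + r, max_iter = max_iter, tol = tol))
    lab <- nmf_labels(fit)
    run_labels[r, ] <- lab
    ind <- outer(lab, lab, `==`)
    consensus <- consensus + ind
    obj <- utils::tail(fit$objective_trace, 1)
    if (obj < best_obj) { best_obj <- obj; best <- fit }
  }
  consensus <- consensus / n_runs
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  coph_d <- stats::cophenetic(hc)
  cophenetic <- if (stats::sd(d) == 0 || stats::sd(coph_d) == 0) 1
                else stats::cor(d, coph_d)
  labels <- stats::cutree(hc, k = k)
  sil <- cluster::silhouette(labels, dist = d)
  silhouette_consensus <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
  rss <- sum((X - best$W %*% best$H)^2)
  structure(list(rank = as.integer(k), consensus = consensus,
                 cophenetic = cophenetic, rss = rss,
                 silhouette_consensus = silhouette_consensus,
                 best_run = best, labels = labels, run_labels = run_labels,
                 hclust = hc),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = %d: cophenetic %.3f, silhouette %.3f, RSS %.4g\n",
              x$rank, x$cophenetic, x$silhouette_consensus, x$rss))
  cat("  cluster sizes:", paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

# delete-one-run jackknife standard errors of the consensus stability metrics
.consensus_jackknife <- function(result) {
  n_runs <- nrow(result$run_labels)
  m <- ncol(result$run_labels)
  coph_r <- sil_r <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    lab <- result$run_labels[r, ]
    conn <- outer(lab, lab, `==`)
    cons <- (result$consensus * n_runs - conn) / (n_runs - 1)
    d <- stats::as.dist(1 - cons)
    hc <- stats::hclust(d, method = "average")
    cd <- stats::cophenetic(hc)
    coph_r[r] <- if (stats::sd(d) == 0 || stats::sd(cd) == 0) 1
                 else stats::cor(d, cd)
    sil <- cluster::silhouette(stats::cutree(hc, result$rank), dist = d)
    sil_r[r] <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
  }
  jse <- function(x) sqrt((n_runs - 1) / n_runs * sum((x - mean(x))^2))
  c(cophenetic_se = jse(coph_r), silhouette_se = jse(sil_r))
}

#' Choose the factorization rank from stability metrics
#'
#' Computes a [consensus_cluster()] for every rank in `k_range` and tabulates
#' cophenetic correlation, RSS, RSS drop (`rss(k-1) - rss(k)`, undefined at
#' the smallest rank) and silhouette consensus. Because cophenetic correlation and silhouette are Monte-Carlo
#' estimates over the restarts, each carries a delete-one-run jackknife
#' standard error, and ranks within two standard errors of a metric's maximum
#' count as tied for it. The chosen rank is the smallest k simultaneously in
#' the maximizing tie set of all three criteria; when no rank satisfies all
#' three, the cophenetic tie set takes precedence and is resolved by the
#' largest RSS drop (smallest rank when no drop is defined), with a warning reporting the disagreement. The full
#' metric table is always returned so the choice can be overridden.
#'
#' @inheritParams consensus_cluster
#' @param k_range contiguous range of ranks to evaluate (default `2:10`).
#' @return An object of class `rank_selection`: `metrics` (one row per k,
#'   with jackknife SEs), `chosen_rank`, and `results` (named list of
#'   `consensus_result`s).
#' @export
select_rank <- function(X, k_range = 2:10, n_runs = 30L, seed = 1L,
                        max_iter = 150L, tol = 1e-4) {
  if (inherits(X, "proteomic_matrix")) X <- t(X$values)
  k_range <- sort(unique(as.integer(k_range)))
  if (!all(diff(k_range) == 1)) stop("`k_range` must be contiguous")
  if (max(k_range) >= min(dim(X)))
    stop("`k_range` exceeds the matrix dimensions")
  results <- list()
  se <- matrix(NA_real_, length(k_range), 2)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    results[[as.character(k)]] <-
      consensus_cluster(X, k, n_runs = n_runs, seed = seed + 1000L * k,
                        max_iter = max_iter, tol = tol)
    se[i, ] <- .consensus_jackknife(results[[as.character(k)]])
  }
  metrics <- data.frame(
    k = k_range,
    cophenetic = vapply(results, `[[`, numeric(1), "cophenetic"),
    cophenetic_se = se[, 1],
    rss = vapply(results, `[[`, numeric(1), "rss"),
    silhouette = vapply(results, `[[`, numeric(1), "silhouette_consensus"),
    silhouette_se = se[, 2],
    row.names = NULL)
  metrics$rss_drop <- c(NA_real_, -diff(metrics$rss))
  in_tie <- function(v, v_se) {
    i <- which.max(v)
    v >= v[i] - 2 * sqrt(v_se^2 + v_se[i]^2)
  }
  coph_set <- in_tie(metrics$cophenetic, metrics$cophenetic_se)
  sil_set <- in_tie(metrics$silhouette, metrics$silhouette_se)
  drp_max <- suppressWarnings(max(metrics$rss_drop, na.rm = TRUE))
  drop_set <- !is.na(metrics$rss_drop) &
    metrics$rss_drop >= drp_max - 1e-9 * abs(drp_max)
  cand <- coph_set & sil_set & drop_set
  if (any(cand)) {
    chosen <- metrics$k[which(cand)[1]]
  } else {
    idx <- which(coph_set)
    drp <- metrics$rss_drop[idx]
    drp[is.na(drp)] <- -Inf
    chosen <- if (all(!is.finite(drp))) metrics$k[idx[1]]
              else metrics$k[idx[which.max(drp)]]
    warning("rank-selection criteria disagree; using the cophenetic tie set resolved by RSS drop",
            call. = FALSE)
  }
  structure(list(metrics = metrics, chosen_rank = chosen, results = results),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("<rank_selection> chosen rank:", x$chosen_rank, "\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Assign renumbered subtype labels from a consensus result
#'
#' Takes the consensus-tree labels of a [consensus_cluster()] and renumbers
#' the clusters into reportable subtype indices. With three clusters and CSF
#' p-tau181 available the convention mirrors the tau profile of the subtypes
#' this pipeline targets: the cluster with the highest mean p-tau181 becomes
#' subtype 2 and the remaining two are numbered 1 and 3 by ascending mean
#' p-tau181 (so subtype 1 is tau-lowest and subtype 3 tau-intermediate).
#' Otherwise clusters are numbered by descending size. The renumbering is
#' deterministic given the consensus result and metadata.
#'
#' @param result a `consensus_result` computed on cases only.
#' @param records sample metadata containing `sample_id` and, ideally,
#'   `ptau181`.
#' @return A data frame `sample_id`, `subtype` (integer in `1..k`).
#' @export
assign_subtypes <- function(result, records) {
  stopifnot(inherits(result, "consensus_result"))
  lab <- result$labels
  k <- result$rank
  have_tau <- is.data.frame(records) &&
    all(c("sample_id", "ptau181") %in% names(records))
  if (have_tau) {
    tau <- records$ptau181[match(names(lab), records$sample_id)]
    mean_tau <- tapply(tau, lab, mean, na.rm = TRUE)
  }
  if (k == 3 && have_tau && !anyNA(mean_tau)) {
    ord <- order(mean_tau)              # ascending tau: low, mid, high
    new_index <- integer(k)
    new_index[ord] <- c(1L, 3L, 2L)     # highest tau -> subtype 2
  } else {
    sizes <- table(lab)
    new_index <- integer(k)
    new_index[order(sizes, decreasing = TRUE)] <- seq_len(k)
  }
  data.frame(sample_id = names(lab), subtype = new_index[lab],
             row.names = NULL, stringsAsFactors = FALSE)
}
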