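#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a non-negative proteins-by-samples matrix as `X ~ W %*% H`
#' by the classic multiplicative-update scheme for the generalized
#' Kullback-Leibler divergence `D(X || WH)` — the algorithm standardly used
#' for consensus-based molecular subtyping. Both factors are initialized
#' uniformly at random in (0, 1] from `seed`; denominators are floored at
#' `eps` so updates stay well-defined. The objective is recorded after every
#' iteration and is non-increasing up to floating-point tolerance.
#'
#' @param X non-negative numeric matrix, proteins in rows and samples in
#'   columns, or a `unit_interval` [proteomic_matrix()] (transposed
#'   internally).
#' @param k factorization rank, `2 <= k < min(dim(X))`.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change convergence threshold.
#' @param eps denominator floor.
#' @return An object of class `nmf_factors`: `W` (proteins x k), `H`
#'   (k x samples), `rank`, `objective_trace`, `converged`, `iterations`,
#'   `seed`. A non-converged fit is returned with a warning.
#' @export
nmf_factorize <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-5,
                          eps = 1e-12) {
  if (inherits(X, "proteomic_matrix")) X <- t(X$values)
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  if (anyNA(X)) stop("`X` must be complete (impute before factorizing)")
  if (any(X < 0)) stop("`X` must be non-negative")
  if (all(X == 0)) stop("`X` is all zero; nothing to factorize")
  if (k < 2 || k >= min(dim(X)))
    stop("rank `k` must satisfy 2 <= k < min(dim(X))")
  set.seed(seed)
  n <- nrow(X); m <- ncol(X)
  W0 <- matrix(stats::runif(n * k, min = .Machine$double.eps, max = 1), n, k)
  H0 <- matrix(stats::runif(k * m, min = .Machine$double.eps, max = 1), k, m)
  res <- .nmf_kl_cpp(X, W0, H0, as.integer(max_iter), tol, eps)
  if (!res$converged)
    warning(sprintf("NMF did not converge in %d iterations (rank %d)",
                    max_iter, k))
  rownames(res$W) <- rownames(X)
  colnames(res$H) <- colnames(X)
  structure(list(W = res$W, H = res$H, rank = as.integer(k),
                 objective_trace = res$objective_trace,
                 converged = res$converged, iterations = res$iterations,
                 seed = as.integer(seed)),
            class = "nmf_factors")
}

#' @export
print.nmf_factors <- function(x, ...) {
  cat(sprintf("<nmf_factors> rank %d, %d x %d, KL divergence %.4g (%d iterations%s)\n",
              x$rank, nrow(x$W), ncol(x$H),
              utils::tail(x$objective_trace, 1), x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Cluster labels from NMF coefficients
#'
#' Assigns each sample to the basis component with the largest coefficient in
#' `H` (ties resolve to the lowest component index).
#'
#' @param factors an `nmf_factors` object.
#' @return Integer vector of labels in `1..rank`, named by sample.
#' @export
nmf_labels <- function(factors) {
  stopifnot(inherits(factors, "nmf_factors"))
  lab <- max.col(t(factors$H), ties.method = "first")
  names(lab) <- colnames(factors$H)
  lab
}
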