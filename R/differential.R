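#' Per-protein subtype-versus-control linear models
#'
#' Fits, for every protein, an ordinary least-squares model
#' `protein ~ group + covariates` where `group` is a single categorical
#' predictor with the controls as reference level and one level per subtype.
#' The per-subtype coefficient is the covariate-adjusted mean difference from
#' controls in z-units; its two-sided t-test p-value is corrected by
#' Benjamini-Hochberg within each subtype across proteins. All proteins share
#' one design matrix, so the fit is a single QR pass.
#'
#' @param zmatrix a z-scored [proteomic_matrix()].
#' @param records sample metadata with `sample_id`, `at_label`, `subtype`
#'   (integer, `NA` for controls) and the covariate columns.
#' @param covariates covariate column names (default `age`, `sex`).
#' @param q_threshold significance threshold on q deciding `direction`.
#' @return A `signature_table` data frame: `protein`, `gene`, `subtype`,
#'   `beta`, `se`, `p`, `q`, `direction` (`up`/`down`/`ns`).
#' @export
differential_vs_control <- function(zmatrix, records,
                                    covariates = c("age", "sex"),
                                    q_threshold = 0.05) {
  stopifnot(inherits(zmatrix, "proteomic_matrix"))
  if (zmatrix$scale_state != "zscore")
    stop("differential models expect a z-scored matrix")
  rec <- records[match(rownames(zmatrix$values), records$sample_id), ]
  grp <- ifelse(rec$at_label == "control", "control",
                ifelse(rec$at_label == "AD" & !is.na(rec$subtype),
                       paste0("s", rec$subtype), NA))
  keep <- !is.na(grp)
  grp <- factor(grp[keep],
                levels = c("control", sort(unique(grp[keep & grp != "control"]))))
  if (nlevels(grp) < 2 || sum(grp == "control") == 0)
    stop("need controls plus at least one subtype")
  df <- data.frame(group = grp, rec[keep, covariates, drop = FALSE])
  for (cv in covariates) {
    if (length(unique(df[[cv]])) < 2)
      stop("rank-deficient design; collinear column(s): ", cv)
  }
  X <- stats::model.matrix(~ ., data = df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- zmatrix$values[keep, , drop = FALSE]
  beta <- qr.coef(qr_x, Y)
  res <- qr.resid(qr_x, Y)
  dfree <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / dfree
  xtx_inv <- chol2inv(chol(crossprod(X)))
  map <- zmatrix$analyte_map
  genes <- map$gene_symbol[match(colnames(Y), map$analyte_id)]
  genes[is.na(genes)] <- colnames(Y)[is.na(genes)]
  sub_levels <- levels(grp)[-1]
  out <- do.call(rbind, lapply(sub_levels, function(s) {
    term <- paste0("group", s)
    j <- match(term, colnames(X))
    b <- beta[j, ]
    se <- sqrt(xtx_inv[j, j] * s2)
    p <- 2 * stats::pt(-abs(b / se), dfree)
    q <- stats::p.adjust(p, method = "BH")
    data.frame(protein = colnames(Y), gene = genes,
               subtype = as.integer(sub("^s", "", s)),
               beta = unname(b), se = unname(se), p = unname(p),
               q = unname(q), stringsAsFactors = FALSE)
  }))
  out$direction <- ifelse(out$q >= q_threshold, "ns",
                          ifelse(out$beta > 0, "up", "down"))
  rownames(out) <- NULL
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, reported in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`; `NA`/`NaN` is an
#'   error.
#' @return q-values aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues)) stop("p-values must not contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Split a signature table into up/down gene lists per subtype
#'
#' For each subtype, collects the genes of proteins significantly above
#' (`q < q_threshold`, `beta > 0`) and below (`beta < 0`) the control level,
#' de-duplicated (several proteins may map to one gene).
#'
#' @param table a `signature_table` from [differential_vs_control()].
#' @param q_threshold FDR threshold (default 0.05).
#' @return Named list, one element per subtype (`s1`, `s2`, ...), each with
#'   character vectors `up` and `down`.
#' @export
split_signatures <- function(table, q_threshold = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("gene", "subtype", "beta", "q") %in% names(table)))
  subs <- sort(unique(table$subtype))
  out <- lapply(subs, function(s) {
    t_s <- table[table$subtype == s & table$q < q_threshold, ]
    list(up = unique(t_s$gene[t_s$beta > 0]),
         down = unique(t_s$gene[t_s$beta < 0]))
  })
  stats::setNames(out, paste0("s", subs))
}

#' Gene-set collection with an explicit background universe
#'
#' @param sets named list of character vectors of gene symbols; genes outside
#'   the background are removed from each set.
#' @param background character vector, the gene universe (e.g. all genes
#'   encoding the assayed proteins).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background) {
  stopifnot(is.list(sets), !is.null(names(sets)), is.character(background))
  background <- unique(background)
  sets <- lapply(sets, function(s) unique(intersect(s, background)))
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (tab-separated: set name, description, genes).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Fisher's-exact over-representation analysis
#'
#' Tests each gene set for over-representation of `genes` within the
#' collection's background by a one-sided (greater) Fisher's exact test on
#' the 2x2 table (in-list & in-set, in-list & out, out-of-list & in-set,
#' out & out), with Benjamini-Hochberg correction across sets. Genes outside
#' the background are dropped with a warning; an empty gene list yields an
#' empty result.
#'
#' @param genes character vector of hit genes.
#' @param collection a [gene_set_collection()].
#' @return Data frame `set`, `overlap`, `set_size`, `odds_ratio`, `p`, `q`,
#'   one row per set, in collection order.
#' @export
fisher_enrichment <- function(genes, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- unique(genes)
  outside <- setdiff(genes, collection$background)
  if (length(outside) > 0) {
    warning(length(outside), " gene(s) outside the background dropped")
    genes <- setdiff(genes, outside)
  }
  if (length(genes) == 0)
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  n_bg <- length(collection$background)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    a <- length(intersect(genes, set))
    b <- length(genes) - a
    c_ <- length(set) - a
    d <- n_bg - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                             alternative = "greater")
    data.frame(set = nm, overlap = a, set_size = length(set),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Write a signature table as TSV
#'
#' @param table a `signature_table` from [differential_vs_control()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_signatures <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
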