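#' Train a subtype-transfer classifier on the discovery cohort
#'
#' Trains a random forest on the discovery z-scored protein matrix restricted
#' to the proteins shared with a replication panel, so the frozen model can
#' be applied to an external cohort with no retraining. The shared panel,
#' class order and out-of-bag accuracy are stored with the model.
#'
#' @param discovery_z z-scored [proteomic_matrix()] (or plain matrix, samples
#'   x proteins) of the discovery cases.
#' @param subtype_labels integer/character subtype labels, named by sample id
#'   or aligned with the rows.
#' @param replication_panel protein ids available on the replication
#'   platform; the model uses the intersection with the discovery proteins
#'   (default: all discovery proteins).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; retraining with the same seed reproduces the
#'   forest exactly.
#' @return Object of class `transfer_model`: `shared_proteins` (ordered
#'   panel), `forest`, `class_order`, `oob_accuracy`, `n_trees`, `seed`.
#' @export
train_transfer_model <- function(discovery_z, subtype_labels,
                                 replication_panel = NULL, n_trees = 500L,
                                 seed = 1L) {
  if (inherits(discovery_z, "proteomic_matrix")) {
    if (discovery_z$scale_state != "zscore")
      stop("discovery matrix must be z-scored")
    discovery_z <- discovery_z$values
  }
  if (is.null(replication_panel)) replication_panel <- colnames(discovery_z)
  panel <- intersect(colnames(discovery_z), replication_panel)
  if (length(panel) == 0) stop("no proteins shared with the replication panel")
  if (length(panel) < 10)
    warning("only ", length(panel), " shared proteins; transfer may be unstable")
  if (!is.null(names(subtype_labels)))
    subtype_labels <- subtype_labels[rownames(discovery_z)]
  y <- factor(subtype_labels)
  X <- discovery_z[, panel, drop = FALSE]
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = y, ntree = n_trees)
  oob <- 1 - forest$err.rate[n_trees, "OOB"]
  structure(list(shared_proteins = panel, forest = forest,
                 class_order = levels(y), oob_accuracy = unname(oob),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("<transfer_model> %d shared proteins, %d trees, OOB accuracy %.3f\n",
              length(x$shared_proteins), x$n_trees, x$oob_accuracy))
  invisible(x)
}

#' Predict subtype membership in a replication cohort
#'
#' Applies a frozen [train_transfer_model()] to a replication matrix that was
#' z-scored within its own cohort. Every panel protein must be present — a
#' missing protein is an error, never silently imputed. Each sample is
#' assigned the subtype with the highest predicted probability; exact
#' probability ties resolve to the lowest subtype index and are flagged.
#'
#' @param model a `transfer_model`.
#' @param replication_z z-scored [proteomic_matrix()] (or matrix) of the
#'   replication cases.
#' @return Data frame `sample_id`, one probability column per subtype
#'   (`prob_1`, ...), `subtype` (assigned), `tie` (logical).
#' @export
predict_subtypes <- function(model, replication_z) {
  stopifnot(inherits(model, "transfer_model"))
  if (inherits(replication_z, "proteomic_matrix")) {
    if (replication_z$scale_state != "zscore")
      stop("replication matrix must be z-scored within its own cohort")
    replication_z <- replication_z$values
  }
  missing <- setdiff(model$shared_proteins, colnames(replication_z))
  if (length(missing) > 0)
    stop("replication matrix lacks panel protein(s): ",
         paste(missing, collapse = ", "))
  X <- replication_z[, model$shared_proteins, drop = FALSE]
  prob <- stats::predict(model$forest, newdata = X, type = "prob")
  prob <- prob[, model$class_order, drop = FALSE]
  assigned <- max.col(prob, ties.method = "first")
  tie <- rowSums(prob == prob[cbind(seq_len(nrow(prob)), assigned)]) > 1
  out <- data.frame(sample_id = rownames(X), stringsAsFactors = FALSE)
  for (j in seq_along(model$class_order))
    out[[paste0("prob_", model$class_order[j])]] <- unname(prob[, j])
  out$subtype <- as.integer(as.character(
    factor(assigned, levels = seq_along(model$class_order),
           labels = model$class_order)))
  out$tie <- tie
  out
}

#' Transfer subtypes from a fitted discovery model to a replication cohort
#'
#' Convenience method implementing the replication protocol around a
#' [csf_subtype()] fit: a random forest is trained on the discovery cases'
#' z-scores restricted to the proteins the replication matrix shares, then
#' applied to the replication matrix (no retraining). Returns the per-sample
#' probabilities and assignments of [predict_subtypes()], with the trained
#' `transfer_model` attached as attribute `"model"`.
#'
#' @param object a `csf_subtype` fit.
#' @param newdata z-scored [proteomic_matrix()] of the replication cases,
#'   normalized within its own cohort.
#' @param n_trees,seed forest parameters (seed defaults to the fit's seed).
#' @param ... unused.
#' @export
predict.csf_subtype <- function(object, newdata, n_trees = 500L,
                                seed = object$seed, ...) {
  if (inherits(newdata, "proteomic_matrix")) {
    panel <- colnames(newdata$values)
  } else panel <- colnames(newdata)
  labels <- stats::setNames(object$subtypes$subtype, object$subtypes$sample_id)
  model <- train_transfer_model(object$case_z, labels,
                                replication_panel = panel,
                                n_trees = n_trees, seed = seed)
  out <- predict_subtypes(model, newdata)
  attr(out, "model") <- model
  out
}
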