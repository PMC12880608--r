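# Clinical contrasts between subtypes: Cox progression models with
# proportional-hazards diagnostics, cross-sectional linear models, and
# linear mixed models for longitudinal decline.

# merge outcome records with metadata; derive apoe4_carrier when needed
.clinical_frame <- function(records, covariates) {
  if ("apoe4_carrier" %in% covariates && !("apoe4_carrier" %in% names(records))) {
    if (!("apoe4_count" %in% names(records)))
      stop("need `apoe4_carrier` or `apoe4_count` in records")
    records$apoe4_carrier <- as.integer(records$apoe4_count > 0)
  }
  miss <- setdiff(covariates, names(records))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    v <- records[[cv]]
    v_num <- if (is.numeric(v)) v else as.numeric(factor(v))
    if (stats::var(v_num, na.rm = TRUE) == 0)
      stop("covariate with zero variance: ", cv)
  }
  records
}

# all pairwise contrasts of a factor's levels from coef/vcov of a model with
# treatment coding; returns estimate (level_i - level_j), se, z/t p
.pairwise_contrasts <- function(beta, vcov, levels, prefix, p_fun) {
  terms <- paste0(prefix, levels[-1])
  k <- length(levels)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (i == 1) {                      # level j vs reference
        t_j <- terms[j - 1]
        est <- beta[[t_j]]
        se <- sqrt(vcov[t_j, t_j])
      } else {                           # difference of two non-reference levels
        t_i <- terms[i - 1]; t_j <- terms[j - 1]
        est <- beta[[t_j]] - beta[[t_i]]
        se <- sqrt(vcov[t_j, t_j] + vcov[t_i, t_i] - 2 * vcov[t_j, t_i])
      }
      out[[length(out) + 1]] <- data.frame(
        contrast = paste0(levels[j], " - ", levels[i]),
        estimate = est, se = se, p = p_fun(est, se),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Cox proportional-hazards contrasts of progression to dementia
#'
#' Fits a Cox model for time to dementia conversion with subtype as a
#' categorical predictor, adjusted for the given covariates, using Efron tie
#' handling. Reports every pairwise subtype log-hazard contrast with its
#' Wald p-value, Benjamini-Hochberg corrected across the pairwise family.
#' Subjects demented at baseline must already be absent from `survival`.
#'
#' @param survival data frame `sample_id`, `time_years` (> 0), `event`
#'   (1 converted / 0 censored).
#' @param records metadata with `sample_id`, `subtype` and covariates.
#' @param covariates covariate columns (default age, sex, education,
#'   apoe4_carrier; the carrier indicator is derived from `apoe4_count` when
#'   absent).
#' @return Object of class `cox_contrasts`: `fit` (the `coxph` object),
#'   `contrasts` (pairwise data frame with `hr = exp(estimate)`), `n`,
#'   `events`.
#' @export
fit_cox <- function(survival, records,
                    covariates = c("age", "sex", "education", "apoe4_carrier")) {
  stopifnot(all(c("sample_id", "time_years", "event") %in% names(survival)))
  records <- .clinical_frame(records, covariates)
  d <- merge(survival, records, by = "sample_id")
  d <- d[!is.na(d$subtype), ]
  d$subtype <- factor(paste0("s", d$subtype))
  if (nlevels(d$subtype) < 2) stop("need at least two subtypes")
  ev <- tapply(d$event, d$subtype, sum)
  if (any(ev == 0))
    stop("subtype(s) with no conversion events (separation): ",
         paste(names(ev)[ev == 0], collapse = ", "))
  fml <- stats::as.formula(paste(
    "survival::Surv(time_years, event) ~",
    paste(c("subtype", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))
  ctr <- .pairwise_contrasts(stats::coef(fit), stats::vcov(fit),
                             levels(d$subtype), "subtype", wald_p)
  ctr$hr <- exp(ctr$estimate)
  structure(list(fit = fit, contrasts = ctr, n = nrow(d),
                 events = sum(d$event)),
            class = "cox_contrasts")
}

#' @export
print.cox_contrasts <- function(x, ...) {
  cat(sprintf("<cox_contrasts> %d subjects, %d events\n", x$n, x$events))
  print(x$contrasts[, c("contrast", "hr", "se", "p", "q")], digits = 4)
  invisible(x)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Correlates the scaled Schoenfeld residuals of a fitted Cox model with the
#' rank of event time (score test per covariate plus a global test). All
#' per-term and global p-values above 0.05 is reported as no violation.
#'
#' @param fit a `coxph` fit or a [fit_cox()] result.
#' @return Object of class `schoenfeld_test`: `table` (term, chisq, df, p),
#'   `global_p`, `no_violation`.
#' @export
schoenfeld_test <- function(fit) {
  if (inherits(fit, "cox_contrasts")) fit <- fit$fit
  stopifnot(inherits(fit, "coxph"))
  n_events <- fit$nevent
  if (is.null(n_events) || n_events < 3)
    stop("Schoenfeld test needs at least 3 events")
  z <- tryCatch(survival::cox.zph(fit, transform = "rank"),
                error = function(e)
                  stop("Schoenfeld test undefined: ", conditionMessage(e)))
  tab <- as.data.frame(z$table)
  names(tab) <- c("chisq", "df", "p")
  tab <- cbind(term = rownames(tab), tab)
  rownames(tab) <- NULL
  if (anyNA(tab$p))
    stop("Schoenfeld test undefined (degenerate residuals)")
  global_p <- tab$p[tab$term == "GLOBAL"]
  structure(list(table = tab[tab$term != "GLOBAL", ], global_p = global_p,
                 no_violation = all(tab$p > 0.05)),
            class = "schoenfeld_test")
}

#' @export
print.schoenfeld_test <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("GLOBAL p = %.4g -> %s\n", x$global_p,
              if (x$no_violation) "no violation of proportional hazards"
              else "possible proportional-hazards violation"))
  invisible(x)
}

#' Baseline cross-sectional subtype contrasts
#'
#' Ordinary least-squares model of a baseline outcome on the group factor
#' plus covariates, with every pairwise group contrast (two-sided t, BH
#' corrected within the outcome family). Groups are the subtypes; with
#' `include_controls = TRUE` the controls join as reference group (used for
#' volume-vs-control comparisons, where estimated total intracranial volume
#' is typically appended to `covariates`).
#'
#' @param values named numeric vector of the outcome (names = sample ids) or
#'   the name of a column of `records`.
#' @param records metadata with `sample_id`, `subtype` and covariates.
#' @param covariates covariate columns.
#' @param include_controls include `subtype = NA` samples as a control group.
#' @return Object of class `baseline_contrasts`: `fit`, `contrasts`,
#'   `adjusted_means`.
#' @export
baseline_contrasts <- function(values, records,
                               covariates = c("age", "sex", "education",
                                              "apoe4_carrier"),
                               include_controls = FALSE) {
  records <- .clinical_frame(records, covariates)
  if (is.character(values) && length(values) == 1)
    values <- stats::setNames(records[[values]], records$sample_id)
  d <- records
  d$.y <- values[match(d$sample_id, names(values))]
  d$group <- ifelse(is.na(d$subtype), if (include_controls) "control" else NA,
                    paste0("s", d$subtype))
  d <- d[!is.na(d$group) & !is.na(d$.y), ]
  lev <- sort(unique(d$group))
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  d$group <- factor(d$group, levels = lev)
  if (nlevels(d$group) < 2) stop("need at least two groups with outcome data")
  fml <- stats::as.formula(paste(
    ".y ~", paste(c("group", covariates), collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  dfree <- fit$df.residual
  t_p <- function(est, se) 2 * stats::pt(-abs(est / se), dfree)
  ctr <- .pairwise_contrasts(stats::coef(fit), stats::vcov(fit),
                             levels(d$group), "group", t_p)
  # covariate-adjusted group means at the covariate means
  mm <- stats::model.matrix(fit)
  mean_row <- colMeans(mm)
  adj <- vapply(levels(d$group), function(g) {
    r <- mean_row
    r[grep("^group", names(r))] <- 0
    if (g != levels(d$group)[1]) r[paste0("group", g)] <- 1
    sum(r * stats::coef(fit))
  }, numeric(1))
  structure(list(fit = fit, contrasts = ctr, adjusted_means = adj),
            class = "baseline_contrasts")
}

#' @export
print.baseline_contrasts <- function(x, ...) {
  cat("<baseline_contrasts> adjusted group means:\n")
  print(round(x$adjusted_means, 3))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Longitudinal decline slopes by linear mixed models
#'
#' Fits `outcome ~ time * group + covariates` with subject-level random
#' intercepts and random time slopes (REML). Per-group mean slopes come from
#' the time main effect and the time-by-group interactions; every pairwise
#' slope difference is tested (Satterthwaite degrees of freedom) and BH
#' corrected within the outcome family. If the random-slope model fails to
#' converge the model falls back to random intercepts only, with a warning.
#'
#' @param visits long-format data frame `sample_id`, `time_years`, and the
#'   outcome column.
#' @param records metadata with `sample_id`, `subtype` and covariates.
#' @param covariates covariate columns.
#' @param outcome name of the outcome column in `visits`.
#' @return Object of class `slope_contrasts`: `slopes` (per-group estimate
#'   and se), `contrasts` (pairwise slope differences), `fit`.
#' @export
longitudinal_slopes <- function(visits, records,
                                covariates = c("age", "sex", "education",
                                               "apoe4_carrier"),
                                outcome = "cognitive_score") {
  stopifnot(all(c("sample_id", "time_years", outcome) %in% names(visits)))
  records <- .clinical_frame(records, covariates)
  d <- merge(visits[, c("sample_id", "time_years", outcome)],
             records, by = "sample_id")
  d <- d[!is.na(d$subtype) & !is.na(d[[outcome]]), ]
  d$group <- factor(paste0("s", d$subtype))
  nv <- table(d$sample_id)
  if (all(nv < 2))
    stop("all subjects have a single visit; use baseline_contrasts()")
  if (mean(nv >= 2) < 0.5)
    stop("fewer than half the subjects have >= 2 visits")
  d$.y <- d[[outcome]]
  fml <- stats::as.formula(paste(
    ".y ~", paste(c("time_years * group", covariates,
                    "(1 + time_years | sample_id)"), collapse = " + ")))
  fit <- tryCatch({
    f <- lmerTest::lmer(fml, data = d, REML = TRUE)
    if (length(f@optinfo$conv$lme4$messages) > 0) stop("convergence failure")
    f
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    warning("random-slope model did not converge; falling back to random intercepts")
    fml2 <- stats::as.formula(paste(
      ".y ~", paste(c("time_years * group", covariates,
                      "(1 | sample_id)"), collapse = " + ")))
    fit <- lmerTest::lmer(fml2, data = d, REML = TRUE)
  }
  beta <- lme4::fixef(fit)
  lev <- levels(d$group)
  terms <- c("time_years", paste0("time_years:group", lev[-1]))
  # per-group slope = time effect (+ interaction for non-reference groups)
  L <- matrix(0, length(lev), length(beta),
              dimnames = list(lev, names(beta)))
  L[, "time_years"] <- 1
  for (i in seq_along(lev[-1])) L[i + 1, terms[i + 1]] <- 1
  V <- as.matrix(stats::vcov(fit))
  slopes <- data.frame(group = lev,
                       slope = as.numeric(L %*% beta),
                       se = sqrt(diag(L %*% V %*% t(L))),
                       stringsAsFactors = FALSE)
  # pairwise slope differences with Satterthwaite df via contest
  pairs <- utils::combn(seq_along(lev), 2)
  ctr <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    lvec <- L[j, ] - L[i, ]
    tst <- lmerTest::contest(fit, lvec, joint = FALSE)
    data.frame(contrast = paste0(lev[j], " - ", lev[i]),
               estimate = tst$Estimate, se = tst$`Std. Error`,
               p = tst$`Pr(>|t|)`, stringsAsFactors = FALSE)
  }))
  ctr$q <- bh_fdr(ctr$p)
  rownames(ctr) <- NULL
  structure(list(slopes = slopes, contrasts = ctr, fit = fit),
            class = "slope_contrasts")
}

#' @export
print.slope_contrasts <- function(x, ...) {
  cat("<slope_contrasts> per-group slopes (units/year):\n")
  print(x$slopes, digits = 4)
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Kaplan-Meier curves per subtype, in exportable long format
#'
#' Computes the product-limit survival estimate of time to dementia
#' conversion within each subtype, as a plain data frame suitable for
#' `write.csv`.
#'
#' @param survival data frame `sample_id`, `time_years`, `event`.
#' @param records metadata with `sample_id` and `subtype`.
#' @return Data frame `subtype`, `time_years`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curves <- function(survival, records) {
  d <- merge(survival, records[, c("sample_id", "subtype")], by = "sample_id")
  d <- d[!is.na(d$subtype), ]
  do.call(rbind, lapply(sort(unique(d$subtype)), function(s) {
    ds <- d[d$subtype == s, ]
    km <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = ds)
    data.frame(subtype = s, time_years = km$time, n_risk = km$n.risk,
               n_event = km$n.event, survival = km$surv)
  }))
}
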