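sim_surv_records <- function(n_per, hr = 3, seed = 31, censor = Inf) {
  set.seed(seed)
  n <- 2 * n_per
  grp <- rep(1:2, each = n_per)
  rate <- 0.1 * hr^(grp - 1)
  t_ev <- stats::rexp(n, rate)
  surv <- data.frame(sample_id = sprintf("s%04d", 1:n),
                     time_years = pmin(t_ev, censor),
                     event = as.integer(t_ev <= censor))
  rec <- data.frame(sample_id = surv$sample_id, subtype = grp,
                    age = stats::rnorm(n, 73, 7),
                    sex = sample(c("female", "male"), n, TRUE),
                    education = round(stats::rnorm(n, 16, 3)),
                    apoe4_count = sample(0:2, n, TRUE))
  list(survival = surv, records = rec)
}

test_that("Cox beta matches a grid-search partial-likelihood maximizer", {
  surv <- data.frame(sample_id = sprintf("a%d", 1:6),
                     time_years = c(1, 2, 3, 4, 5, 6),
                     event = 1L)
  rec <- data.frame(sample_id = surv$sample_id,
                    subtype = c(1, 2, 1, 2, 1, 2))
  fit <- fit_cox(surv, rec, covariates = character(0))
  x <- c(0, 1, 0, 1, 0, 1)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_loglik, numeric(1),
               time = surv$time_years, event = surv$event, x = x)
  beta_grid <- grid[which.max(ll)]
  beta_fit <- fit$contrasts$estimate[fit$contrasts$contrast == "s2 - s1"]
  expect_equal(beta_fit, beta_grid, tolerance = 1e-4)
  # returned beta is a local maximum of the hand-coded likelihood
  expect_gte(cox_loglik(beta_fit, surv$time_years, surv$event, x),
             cox_loglik(beta_fit + 0.1, surv$time_years, surv$event, x))
  expect_gte(cox_loglik(beta_fit, surv$time_years, surv$event, x),
             cox_loglik(beta_fit - 0.1, surv$time_years, surv$event, x))
})

test_that("relabelling groups flips the contrast sign exactly", {
  d <- sim_surv_records(40)
  f1 <- fit_cox(d$survival, d$records)
  rec_flip <- d$records
  rec_flip$subtype <- 3 - rec_flip$subtype
  f2 <- fit_cox(d$survival, rec_flip)
  expect_equal(f1$contrasts$estimate[1], -f2$contrasts$estimate[1],
               tolerance = 1e-10)
})

test_that("hazard-ratio recovery and 1/sqrt(n) SE scaling hold in simulation", {
  d <- sim_surv_records(200, hr = 3)
  f <- fit_cox(d$survival, d$records)
  ct <- f$contrasts[f$contrasts$contrast == "s2 - s1", ]
  expect_lt(abs(ct$estimate - log(3)), 3 * ct$se)
  d8 <- sim_surv_records(400, hr = 3, seed = 77)
  f8 <- fit_cox(d8$survival, d8$records)
  ratio <- ct$se / f8$contrasts$se[f8$contrasts$contrast == "s2 - s1"]
  expect_gt(ratio, 1.1); expect_lt(ratio, 1.8)   # ~ sqrt(2) expected
})

test_that("degenerate survival inputs are rejected with diagnostics", {
  d <- sim_surv_records(30)
  d$survival$event[d$records$subtype == 2] <- 0
  expect_error(fit_cox(d$survival, d$records), "separation")
  d2 <- sim_surv_records(30)
  d2$records$education <- 16
  expect_error(fit_cox(d2$survival, d2$records), "zero variance.*education")
})

test_that("Schoenfeld test flags time-varying effects and rejects degenerate fits", {
  # effect reverses mid-follow-up -> strong violation
  set.seed(41)
  n <- 500
  grp <- rep(0:1, each = n / 2)
  t1 <- stats::rexp(n, 0.5 * exp(2 * grp))       # early: strong positive effect
  t_ev <- ifelse(t1 < 1, t1, 1 + stats::rexp(n, 0.5 * exp(-2 * grp)))
  surv <- data.frame(sample_id = sprintf("v%03d", 1:n),
                     time_years = t_ev, event = 1L)
  rec <- data.frame(sample_id = surv$sample_id, subtype = grp + 1)
  fit <- fit_cox(surv, rec, covariates = character(0))
  sch <- schoenfeld_test(fit)
  expect_lt(sch$global_p, 0.05)
  expect_false(sch$no_violation)

  tiny <- data.frame(sample_id = c("a", "b", "c"),
                     time_years = 1:3, event = c(1, 1, 0))
  rec3 <- data.frame(sample_id = c("a", "b", "c"), subtype = c(1, 2, 1))
  f3 <- fit_cox(tiny, rec3, covariates = character(0))
  expect_error(schoenfeld_test(f3), "at least 3 events")
})

test_that("baseline contrasts recover planted orderings and are antisymmetric", {
  set.seed(51)
  n_per <- 60
  rec <- data.frame(sample_id = sprintf("b%03d", 1:(3 * n_per)),
                    subtype = rep(1:3, each = n_per),
                    age = stats::rnorm(3 * n_per, 73, 7),
                    sex = sample(c("female", "male"), 3 * n_per, TRUE),
                    education = round(stats::rnorm(3 * n_per, 16, 3)),
                    apoe4_count = sample(0:2, 3 * n_per, TRUE))
  mmse <- c(28, 27, 25.5)[rec$subtype] + stats::rnorm(3 * n_per, sd = 1.5)
  names(mmse) <- rec$sample_id
  bc <- baseline_contrasts(mmse, rec)
  expect_true(bc$adjusted_means["s1"] > bc$adjusted_means["s2"])
  expect_true(bc$adjusted_means["s2"] > bc$adjusted_means["s3"])
  est31 <- bc$contrasts$estimate[bc$contrasts$contrast == "s3 - s1"]
  # antisymmetry under relabelling s1 <-> s3
  rec_fl <- rec
  rec_fl$subtype <- 4 - rec$subtype
  bc_fl <- baseline_contrasts(mmse, rec_fl)
  expect_equal(est31,
               -bc_fl$contrasts$estimate[bc_fl$contrasts$contrast == "s3 - s1"],
               tolerance = 1e-10)
  # null outcome: no q below 0.05 expected at these sizes most of the time;
  # just check estimates are near zero
  null_y <- stats::setNames(stats::rnorm(3 * n_per), rec$sample_id)
  bc0 <- baseline_contrasts(null_y, rec)
  expect_true(all(abs(bc0$contrasts$estimate) < 0.75))
})

test_that("mixed-model slopes match per-subject OLS means on balanced data", {
  set.seed(61)
  n_per <- 40
  times <- 0:4
  rec <- data.frame(sample_id = sprintf("l%03d", 1:(3 * n_per)),
                    subtype = rep(1:3, each = n_per))
  slopes <- c(-0.5, -1.0, -1.5)
  vis <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    b0 <- stats::rnorm(1, 28, 1); b1 <- stats::rnorm(1, slopes[rec$subtype[i]], 0.1)
    data.frame(sample_id = rec$sample_id[i], time_years = times,
               cognitive_score = b0 + b1 * times + stats::rnorm(5, sd = 1))
  }))
  ls <- longitudinal_slopes(vis, rec, covariates = character(0))
  # two-stage oracle: group means of per-subject OLS slopes
  subj_slope <- vapply(split(vis, vis$sample_id), function(dd)
    stats::coef(stats::lm(cognitive_score ~ time_years, dd))[2], numeric(1))
  stage2 <- tapply(subj_slope, rec$subtype[match(names(subj_slope),
                                                 rec$sample_id)], mean)
  expect_equal(ls$slopes$slope, as.numeric(stage2), tolerance = 1e-6)
  # planted slope differences recovered within 3 SE
  ct <- ls$contrasts
  expect_lt(abs(ct$estimate[ct$contrast == "s2 - s1"] - (-0.5)),
            3 * ct$se[ct$contrast == "s2 - s1"])
  expect_lt(abs(ct$estimate[ct$contrast == "s3 - s1"] - (-1.0)),
            3 * ct$se[ct$contrast == "s3 - s1"])

  # single-visit data are redirected
  vis1 <- vis[vis$time_years == 0, ]
  expect_error(longitudinal_slopes(vis1, rec, covariates = character(0)),
               "baseline_contrasts")
})

test_that("null longitudinal effects give near-zero slope differences", {
  set.seed(71)
  n_per <- 30
  rec <- data.frame(sample_id = sprintf("n%03d", 1:(2 * n_per)),
                    subtype = rep(1:2, each = n_per))
  vis <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    data.frame(sample_id = rec$sample_id[i], time_years = 0:3,
               cognitive_score = stats::rnorm(4, 28, 1))
  }))
  ls <- longitudinal_slopes(vis, rec, covariates = character(0))
  ct <- ls$contrasts
  expect_lt(abs(ct$estimate[1]), 3 * ct$se[1])
})

test_that("Kaplan-Meier export matches survfit step functions", {
  d <- sim_surv_records(40, censor = 15)
  km <- km_curves(d$survival, d$records)
  expect_setequal(unique(km$subtype), 1:2)
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  ds <- merge(d$survival, d$records)[merge(d$survival, d$records)$subtype == 1, ]
  ref <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = ds)
  expect_equal(km$survival[km$subtype == 1], ref$surv, tolerance = 1e-12)
})
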