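# Shared fixtures: built in code, memoized across test files within a run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small cohort for fast module tests
small_config <- function(seed = 42L, ...) {
  cohort_config(seed = seed, n_controls = 40L,
                n_per_subtype = c(30L, 40L, 35L), n_proteins = 80L,
                n_informative_per_subtype = 12L, ...)
}

# run preprocessing on a bundle: A/T labels, QC, collapse, control-referenced
# z-scores; returns the pieces downstream stages need
preprocess_bundle <- function(bundle, cfg = bundle$config) {
  rec <- classify_at_framework(bundle$metadata, cfg$abeta_cutoff,
                               cfg$ptau_cutoff)
  rec$subtype <- rec$true_subtype
  ctrl <- rec$sample_id[rec$at_label == "control"]
  ad <- rec$sample_id[rec$at_label == "AD"]
  pm <- filter_missingness(bundle$proteomics)
  pm <- collapse_aptamers(pm, ctrl, ad)
  z <- normalize_to_controls(pm, reference_ids = ctrl)
  list(records = rec, z = z, control_ids = ctrl, case_ids = ad)
}

small_pipeline <- function() memo("small_pipeline", {
  b <- generate_cohort(small_config())
  c(list(bundle = b), preprocess_bundle(b))
})

# full-size discovery fit under the default study conditions; shared by the
# label-recovery and end-to-end acceptance checks
default_fit <- function() memo("default_fit", {
  cfg <- cohort_config(seed = 20260923L)
  b <- generate_cohort(cfg)
  pp <- preprocess_bundle(b)
  fit <- suppressWarnings(
    csf_subtype(pp$z, pp$records, k_range = 2:10, n_runs = 30L, seed = 7L))
  c(list(bundle = b, fit = fit, config = cfg), pp)
})

# independent Kruskal-Wallis oracle: rank formula with tie correction
kw_oracle <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# independent hypergeometric tail oracle for one-sided Fisher tests
fisher_oracle <- function(overlap, list_size, set_size, background) {
  x <- overlap:min(list_size, set_size)
  sum(choose(set_size, x) * choose(background - set_size, list_size - x)) /
    choose(background, list_size)
}

# brute-force BH step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(p[ord][i:m] * m / (i:m))), numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# hand-coded Cox partial log-likelihood (no ties) for grid-search oracles
cox_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
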