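#' Configuration for the synthetic CSF cohort generator
#'
#' Defines the study conditions a generated cohort emulates: an
#' amyloid-negative control group plus three latent case subtypes with
#' subtype-specific protein signatures, subtype-graded dementia hazards,
#' cognitive-decline slopes, and tau-biomarker profiles (subtype 2 highest).
#' Defaults mirror the discovery-cohort structure the pipeline targets:
#' 85 controls and 97/200/168 cases, CSF biomarker means and spreads taken
#' from that cohort's clinical table, and an amyloid cutoff of 1098 pg/ml
#' with a p-tau181 cutoff of 26.64 pg/ml so A/T labelling is deterministic.
#'
#' @param seed integer seed; every draw in [generate_cohort()] descends from it.
#' @param n_controls number of biomarker-negative controls.
#' @param n_per_subtype integer vector of three case counts.
#' @param n_proteins number of simulated proteins.
#' @param n_informative_per_subtype number of proteins shifted in each subtype
#'   (disjoint sets; `3 * n_informative_per_subtype <= n_proteins`).
#' @param effect_size standardized mean shift (z-units on the log2 scale) of an
#'   informative protein in its subtype; signs alternate across proteins.
#' @param noise_sd residual SD of log2 abundance (z-unit reference).
#' @param subtype_hazards three positive dementia-conversion rates, events/year.
#' @param censor_years administrative censoring horizon, years.
#' @param visit_interval_years spacing of longitudinal visits, years.
#' @param cognitive_slopes three mean cognitive decline rates, score units/year
#'   (negative = decline).
#' @param tau_profile three mean CSF p-tau181 levels (pg/ml); the second entry
#'   is largest under the defaults.
#' @param shared_protein_fraction fraction of proteins retained on the
#'   replication platform, in (0, 1].
#' @param missing_protein_fraction fraction of non-informative analytes that
#'   receive injected missingness.
#' @param missing_rate per-analyte missing fraction for those analytes (the
#'   default 0.15 exceeds the 10% QC cutoff, so they are removed by QC).
#' @param multi_aptamer_fraction fraction of proteins measured by two aptamers
#'   (the second attenuates the subtype signal, exercising aptamer collapse).
#' @param abeta_cutoff,ptau_cutoff biomarker cutoffs (pg/ml) the simulated
#'   biomarker draws respect.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_controls = 85L,
                          n_per_subtype = c(97L, 200L, 168L),
                          n_proteins = 200L,
                          n_informative_per_subtype = 25L,
                          effect_size = 1.5,
                          noise_sd = 1,
                          subtype_hazards = c(0.05, 0.10, 0.20),
                          censor_years = 10,
                          visit_interval_years = 1,
                          cognitive_slopes = c(-0.3, -0.6, -1.2),
                          tau_profile = c(15.51, 39.42, 32.16),
                          shared_protein_fraction = 0.8,
                          missing_protein_fraction = 0.02,
                          missing_rate = 0.15,
                          multi_aptamer_fraction = 0.05,
                          abeta_cutoff = 1098,
                          ptau_cutoff = 26.64) {
  cfg <- list(seed = as.integer(seed), n_controls = as.integer(n_controls),
              n_per_subtype = as.integer(n_per_subtype),
              n_proteins = as.integer(n_proteins),
              n_informative_per_subtype = as.integer(n_informative_per_subtype),
              effect_size = effect_size, noise_sd = noise_sd,
              subtype_hazards = subtype_hazards, censor_years = censor_years,
              visit_interval_years = visit_interval_years,
              cognitive_slopes = cognitive_slopes, tau_profile = tau_profile,
              shared_protein_fraction = shared_protein_fraction,
              missing_protein_fraction = missing_protein_fraction,
              missing_rate = missing_rate,
              multi_aptamer_fraction = multi_aptamer_fraction,
              abeta_cutoff = abeta_cutoff, ptau_cutoff = ptau_cutoff)
  .validate_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

.validate_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid configuration: `%s` %s", field, why), call. = FALSE)
  if (length(cfg$seed) != 1L || is.na(cfg$seed) || cfg$seed >= 2^31 - 10)
    bad("seed", "must be a single integer below 2^31 - 10")
  if (cfg$n_controls <= 0L) bad("n_controls", "must be > 0")
  if (length(cfg$n_per_subtype) != 3L || any(cfg$n_per_subtype <= 0L))
    bad("n_per_subtype", "must be three positive counts")
  if (cfg$n_proteins <= 0L) bad("n_proteins", "must be > 0")
  if (cfg$n_informative_per_subtype <= 0L)
    bad("n_informative_per_subtype", "must be > 0")
  if (3L * cfg$n_informative_per_subtype > cfg$n_proteins)
    bad("n_informative_per_subtype", "x 3 must not exceed n_proteins")
  if (cfg$effect_size < 0) bad("effect_size", "must be >= 0")
  if (cfg$noise_sd <= 0) bad("noise_sd", "must be > 0")
  if (length(cfg$subtype_hazards) != 3L || any(cfg$subtype_hazards <= 0))
    bad("subtype_hazards", "must be three strictly positive rates")
  if (cfg$censor_years <= 0) bad("censor_years", "must be > 0")
  if (cfg$visit_interval_years <= 0) bad("visit_interval_years", "must be > 0")
  if (length(cfg$cognitive_slopes) != 3L)
    bad("cognitive_slopes", "must have three entries")
  if (length(cfg$tau_profile) != 3L || any(cfg$tau_profile <= 0))
    bad("tau_profile", "must be three positive pg/ml levels")
  if (cfg$shared_protein_fraction <= 0 || cfg$shared_protein_fraction > 1)
    bad("shared_protein_fraction", "must lie in (0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    bad("missing_rate", "must lie in [0, 1)")
  invisible(cfg)
}

# latent protein layout shared by discovery and replication draws
.protein_layout <- function(cfg) {
  p <- cfg$n_proteins
  protein_ids <- sprintf("P%04d", seq_len(p))
  genes <- sprintf("GENE%04d", seq_len(p))
  mu <- stats::runif(p, 8, 12)              # baseline log2 RFU per protein
  m <- cfg$n_informative_per_subtype
  informative <- lapply(1:3, function(s) protein_ids[((s - 1L) * m + 1L):(s * m)])
  signs <- lapply(1:3, function(s) rep_len(c(1, -1), m))
  n_multi <- round(cfg$multi_aptamer_fraction * p)
  multi <- if (n_multi > 0) sort(sample.int(p, n_multi)) else integer(0)
  # analyte table: proteins in `multi` carry a second, signal-attenuated aptamer
  n_apt <- ifelse(seq_len(p) %in% multi, 2L, 1L)
  map <- data.frame(
    analyte_id = unlist(lapply(seq_len(p), function(i)
      paste0(protein_ids[i], ".", seq_len(n_apt[i])))),
    protein_id = rep(protein_ids, n_apt),
    gene_symbol = rep(genes, n_apt),
    stringsAsFactors = FALSE)
  map$attenuation <- ifelse(grepl("\\.2$", map$analyte_id), 0.5, 1)
  list(protein_ids = protein_ids, mu = mu, informative = informative,
       signs = signs, map = map)
}

# draw one cohort (samples x analytes raw matrix + metadata + outcomes)
.draw_cohort <- function(cfg, layout, prefix) {
  n_case <- sum(cfg$n_per_subtype)
  n <- cfg$n_controls + n_case
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  subtype <- c(rep(NA_integer_, cfg$n_controls),
               rep(1:3, times = cfg$n_per_subtype))

  # per-protein log2 shift for each sample
  p <- cfg$n_proteins
  shift <- matrix(0, n, p, dimnames = list(ids, layout$protein_ids))
  for (s in 1:3) {
    rows <- which(subtype == s)
    cols <- match(layout$informative[[s]], layout$protein_ids)
    shift[rows, cols] <- rep(layout$signs[[s]] * cfg$effect_size * cfg$noise_sd,
                             each = length(rows))
  }

  map <- layout$map
  log2v <- matrix(stats::rnorm(n * nrow(map), sd = cfg$noise_sd), n, nrow(map))
  log2v <- log2v +
    rep(layout$mu[match(map$protein_id, layout$protein_ids)], each = n) +
    shift[, match(map$protein_id, layout$protein_ids)] *
      rep(map$attenuation, each = n)
  dimnames(log2v) <- list(ids, map$analyte_id)
  raw <- 2^log2v

  # missing-at-random injection on non-informative analytes only, so planted
  # truth sets survive the QC filter
  inf_all <- unlist(layout$informative)
  eligible <- which(!(map$protein_id %in% inf_all))
  n_missing <- round(cfg$missing_protein_fraction * nrow(map))
  if (n_missing > 0 && length(eligible) > 0) {
    cols <- sample(eligible, min(n_missing, length(eligible)))
    for (j in cols) {
      k <- max(1L, round(cfg$missing_rate * n))
      raw[sample.int(n, k), j] <- NA_real_
    }
  }

  # covariates, independent of subtype by default
  age <- pmin(pmax(stats::rnorm(n, 73.8, 7.5), 55), 95)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.42, 0.58))
  education <- round(pmin(pmax(stats::rnorm(n, 16, 2.9), 6), 20))
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.55, 0.35, 0.10))

  # CSF biomarkers: amyloid respects the A/T cutoff by construction
  rtrunc <- function(k, mean, sd, lower = -Inf, upper = Inf) {
    x <- stats::rnorm(k, mean, sd)
    while (any(out <- x <= lower | x >= upper))
      x[out] <- stats::rnorm(sum(out), mean, sd)
    x
  }
  is_ctrl <- is.na(subtype)
  abeta <- numeric(n); ptau <- numeric(n); ttau <- numeric(n)
  abeta[is_ctrl] <- rtrunc(sum(is_ctrl), 1661.89, 385.08,
                           lower = cfg$abeta_cutoff)
  ptau[is_ctrl] <- rtrunc(sum(is_ctrl), 18.27, 4.01, lower = 2,
                          upper = cfg$ptau_cutoff)
  ttau[is_ctrl] <- rtrunc(sum(is_ctrl), 209.14, 45.14, lower = 50)
  abeta_mu <- c(712.20, 736.11, 577.43); abeta_sd <- c(240.92, 170.08, 173.68)
  ptau_sd <- c(5.45, 15.74, 12.79)
  ttau_mu <- c(168.01, 386.09, 321.30); ttau_sd <- c(50.75, 137.48, 118.16)
  for (s in 1:3) {
    rows <- which(subtype == s)
    abeta[rows] <- rtrunc(length(rows), abeta_mu[s], abeta_sd[s],
                          lower = 150, upper = cfg$abeta_cutoff)
    ptau[rows] <- rtrunc(length(rows), cfg$tau_profile[s], ptau_sd[s], lower = 2)
    ttau[rows] <- rtrunc(length(rows), ttau_mu[s], ttau_sd[s], lower = 50)
  }

  diagnosis <- rep("CN", n)
  diagnosis[!is_ctrl] <- sample(c("CN", "MCI", "dementia"), n_case,
                                replace = TRUE,
                                prob = c(65, 271, 129) / 465)

  metadata <- data.frame(sample_id = ids, age = age, sex = sex,
                         education = education, apoe4_count = apoe4,
                         diagnosis = diagnosis, abeta42 = abeta,
                         ptau181 = ptau, ttau = ttau,
                         true_subtype = subtype, stringsAsFactors = FALSE)

  # time to dementia conversion; baseline-demented cases are not at risk
  at_risk <- which(!is_ctrl & diagnosis != "dementia")
  ev_time <- stats::rexp(length(at_risk),
                         rate = cfg$subtype_hazards[subtype[at_risk]])
  survival <- data.frame(
    sample_id = ids[at_risk],
    time_years = pmin(ev_time, cfg$censor_years),
    event = as.integer(ev_time <= cfg$censor_years),
    stringsAsFactors = FALSE)

  # longitudinal cognition: subject random intercept/slope around the subtype
  # mean trajectory; controls decline slowly
  times <- seq(0, cfg$censor_years, by = cfg$visit_interval_years)
  base_mean <- ifelse(is_ctrl, 29, c(28, 27, 26)[subtype])
  slope_mean <- ifelse(is_ctrl, -0.05, cfg$cognitive_slopes[subtype])
  b0 <- stats::rnorm(n, 0, 1); b1 <- stats::rnorm(n, 0, 0.1)
  conv_time <- rep(Inf, n)
  conv_time[at_risk][ev_time <= cfg$censor_years] <-
    ev_time[ev_time <= cfg$censor_years]
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    dx <- ifelse(times >= conv_time[i], "dementia", diagnosis[i])
    data.frame(sample_id = ids[i], time_years = times,
               cognitive_score = base_mean[i] + b0[i] +
                 (slope_mean[i] + b1[i]) * times +
                 stats::rnorm(length(times), 0, 1),
               diagnosis = dx, stringsAsFactors = FALSE)
  }))

  proteomics <- proteomic_matrix(raw, "raw",
                                 map[, c("analyte_id", "protein_id",
                                         "gene_symbol")])
  structure(list(proteomics = proteomics, metadata = metadata,
                 visits = visits, survival = survival,
                 truth = list(informative = stats::setNames(layout$informative,
                                                            paste0("s", 1:3)),
                              signs = stats::setNames(layout$signs,
                                                      paste0("s", 1:3))),
                 latent = layout, config = cfg),
            class = "cohort_bundle")
}

#' Generate a synthetic discovery cohort with planted subtype structure
#'
#' Draws controls from a baseline log2-abundance model and cases from one of
#' three latent subtypes. Each subtype shifts its informative proteins by
#' `effect_size` z-units (signs alternating across proteins) on the log2
#' scale; values are exponentiated to pseudo-RFU so downstream log2
#' processing is exercised. Dementia conversion times are exponential with
#' subtype-specific hazards censored at `censor_years`; cognitive scores
#' follow subject-level random intercepts/slopes around subtype mean slopes;
#' CSF amyloid and tau are drawn consistent with the configured cutoffs and
#' tau profile.
#'
#' @param config a [cohort_config()].
#' @return A `cohort_bundle`: `proteomics` (raw [proteomic_matrix()]),
#'   `metadata` (one row per sample, with hidden `true_subtype`), `visits`
#'   (long format), `survival` (time-to-conversion), and `truth` (planted
#'   informative-protein sets and signs per subtype).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) .validate_config(config)
  set.seed(config$seed)
  layout <- .protein_layout(config)
  .draw_cohort(config, layout, "S")
}

#' Derive a synthetic replication cohort on a reduced shared panel
#'
#' Draws a fresh cohort from the same latent model as `bundle` (same
#' informative proteins, signs and baseline means), keeps only a
#' `shared_protein_fraction` subset of proteins, and applies a per-analyte
#' multiplicative scale plus small additive offset to emulate a platform
#' shift. Per-cohort z-scoring removes the multiplicative component exactly.
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()].
#' @param config the [cohort_config()] used for the bundle (its
#'   `shared_protein_fraction` controls the panel size).
#' @return A `cohort_bundle` for the replication cohort; truth labels kept.
#' @export
derive_replication <- function(bundle, config = bundle$config) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!inherits(config, "cohort_config")) .validate_config(config)
  n_keep <- round(config$shared_protein_fraction * config$n_proteins)
  if (n_keep < 2)
    stop("shared_protein_fraction keeps fewer than 2 proteins")
  set.seed(config$seed + 1L)
  rep_bundle <- .draw_cohort(config, bundle$latent, "R")
  keep_prot <- sort(sample(bundle$latent$protein_ids, n_keep))
  map <- rep_bundle$proteomics$analyte_map
  keep_analyte <- map$analyte_id[map$protein_id %in% keep_prot]
  pm <- rep_bundle$proteomics[, keep_analyte]
  # platform shift: per-analyte gain plus a small positive offset
  gain <- 2^stats::runif(ncol(pm), -1, 1)
  offset <- stats::runif(ncol(pm), 0, 5)
  pm$values <- sweep(pm$values, 2, gain, `*`) +
    rep(offset, each = nrow(pm$values))
  rep_bundle$proteomics <- pm
  rep_bundle$shared_proteins <- keep_prot
  rep_bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  n_case <- sum(!is.na(x$metadata$true_subtype))
  cat(sprintf("<cohort_bundle> %d samples (%d cases, %d controls)\n",
              nrow(x$metadata), n_case, nrow(x$metadata) - n_case))
  print(x$proteomics)
  cat(sprintf("  %d visits, %d at-risk survival records\n",
              nrow(x$visits), nrow(x$survival)))
  invisible(x)
}

#' Write a cohort bundle to plain-text files
#'
#' Writes proteomics (samples as rows, analyte-ID header, `NA` for missing),
#' metadata, visits (long format) and survival as CSV, the analyte map as
#' CSV, the planted truth as JSON, and the configuration as YAML.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteomics = file.path(dir, "proteomics.csv"),
             metadata = file.path(dir, "metadata.csv"),
             visits = file.path(dir, "visits.csv"),
             survival = file.path(dir, "survival.csv"),
             analyte_map = file.path(dir, "analyte_map.csv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  prot <- data.frame(sample_id = rownames(bundle$proteomics$values),
                     bundle$proteomics$values, check.names = FALSE)
  utils::write.csv(prot, paths[["proteomics"]], row.names = FALSE, na = "NA")
  utils::write.csv(bundle$metadata, paths[["metadata"]], row.names = FALSE)
  utils::write.csv(bundle$visits, paths[["visits"]], row.names = FALSE)
  utils::write.csv(bundle$survival, paths[["survival"]], row.names = FALSE)
  utils::write.csv(bundle$proteomics$analyte_map, paths[["analyte_map"]],
                   row.names = FALSE)
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = FALSE)
  yaml::write_yaml(unclass(bundle$config), paths[["config"]])
  invisible(paths)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file as written by [write_cohort()] (`config.yaml`).
#' @return A validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
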