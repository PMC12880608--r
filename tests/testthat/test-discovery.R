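test_that("Kruskal-Wallis screening matches the rank-formula oracle", {
  # hand-checkable instance: {1,2,3} vs {4,5,6} -> H = 3.857, p ~ 0.0495
  x <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(c("control", "AD"), each = 3))
  expect_equal(kw_oracle(x, g), 27 / 7, tolerance = 1e-12)
  v <- matrix(x, 6, 2, dimnames = list(sprintf("s%d", 1:6), c("P1", "P2")))
  v[, 2] <- 1  # constant protein
  zm <- proteomic_matrix(v, "zscore")
  sel <- select_ad_proteins(zm, stats::setNames(as.character(g), rownames(v)),
                            alpha = 0.05)
  expect_equal(sel, "P1", ignore_attr = TRUE)
  p <- attr(sel, "p")
  expect_equal(unname(p["P1"]), stats::pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(p["P2"]), 1)   # constant -> H = 0 convention

  # tie-corrected oracle agrees with the implementation on random draws
  set.seed(33)
  for (i in 1:20) {
    xx <- sample(1:6, 14, replace = TRUE)   # forces ties
    gg <- factor(sample(c("a", "b"), 14, replace = TRUE))
    if (nlevels(droplevels(gg)) < 2) next
    expect_equal(unname(stats::kruskal.test(xx, gg)$statistic),
                 kw_oracle(xx, gg), tolerance = 1e-10)
  }
})

test_that("screening retention calibrates to pooled-shift power on the default cohort", {
  # An informative protein for subtype s shifts only that subtype's cases, so
  # the pooled case-vs-control standardized shift is (n_s / n_cases) * effect.
  # Retention should match the corresponding two-sided normal-power oracle.
  fx <- default_fit()
  cfg <- fx$config
  sel <- fx$fit$selected_proteins
  n_case <- sum(cfg$n_per_subtype)
  power_oracle <- vapply(1:3, function(s) {
    shift <- cfg$n_per_subtype[s] / n_case * cfg$effect_size
    frac <- cfg$n_per_subtype[s] / n_case
    sd_case <- sqrt(1 + frac * (1 - frac) * cfg$effect_size^2)
    se <- sqrt(sd_case^2 / n_case + 1 / cfg$n_controls)
    zc <- stats::qnorm(1 - 0.01 / 2)
    stats::pnorm(-zc + shift / se) + stats::pnorm(-zc - shift / se)
  }, numeric(1))
  retention <- vapply(1:3, function(s) {
    mean(fx$bundle$truth$informative[[s]] %in% sel)
  }, numeric(1))
  # binomial noise over 25 proteins per subtype: allow ~3 SE plus rank-test
  # vs normal-approximation slack
  tol <- 3 * sqrt(power_oracle * (1 - power_oracle) / cfg$n_informative_per_subtype) + 0.12
  expect_true(all(abs(retention - power_oracle) < tol))
  # the strongly shifted subtypes are retained nearly completely
  expect_gt(retention[2], 0.9)
  expect_gt(retention[3], 0.8)
})

test_that("unit-interval scaling maps ranges to [0,1] with documented conventions", {
  v <- matrix(c(2, 4, 6, 5, 5, 5), 3, 2,
              dimnames = list(c("a", "b", "c"), c("P1", "P2")))
  zm <- proteomic_matrix(v, "zscore")
  u <- minmax_scale(zm)
  expect_equal(unname(u$values[, "P1"]), c(0, 0.5, 1))
  expect_equal(unname(u$values[, "P2"]), c(0, 0, 0))   # constant -> zeros
  expect_equal(u$scale_state, "unit_interval")
  # affine invariance
  zm2 <- proteomic_matrix(3 * v - 10, "zscore")
  expect_equal(minmax_scale(zm2)$values, u$values, tolerance = 1e-12)
})

test_that("KL-NMF recovers exact-rank structure and keeps its guarantees", {
  set.seed(5)
  W0 <- matrix(stats::runif(20 * 3), 20, 3)
  H0 <- matrix(stats::runif(3 * 15), 3, 15)
  X <- W0 %*% H0
  dimnames(X) <- list(sprintf("p%d", 1:20), sprintf("s%d", 1:15))
  fit <- suppressWarnings(nmf_factorize(X, 3, seed = 2, max_iter = 5000, tol = 0))
  expect_lt(utils::tail(fit$objective_trace, 1), 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  # objective trace non-increasing within numerical tolerance
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
  # validation errors
  expect_error(nmf_factorize(X * 0, 3), "all zero")
  expect_error(nmf_factorize(X, 20), "rank")
  expect_error(nmf_factorize(-X, 3), "non-negative")
})

test_that("dominant-coefficient labels recover a two-block matrix", {
  X <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  dimnames(X) <- list(sprintf("p%d", 1:4), sprintf("s%d", 1:4))
  fit <- nmf_factorize(X, 2, seed = 4, max_iter = 2000, tol = 1e-10)
  lab <- nmf_labels(fit)
  expect_equal(lab[["s1"]], lab[["s2"]])
  expect_equal(lab[["s3"]], lab[["s4"]])
  expect_false(lab[["s1"]] == lab[["s3"]])
})

two_block_matrix <- function(n_per = 10, p_per = 6, noise = 0.02, seed = 8) {
  set.seed(seed)
  X <- matrix(stats::runif(2 * p_per * 2 * n_per, 0, noise),
              2 * p_per, 2 * n_per)
  X[1:p_per, 1:n_per] <- X[1:p_per, 1:n_per] + 1
  X[(p_per + 1):(2 * p_per), (n_per + 1):(2 * n_per)] <-
    X[(p_per + 1):(2 * p_per), (n_per + 1):(2 * n_per)] + 1
  dimnames(X) <- list(sprintf("p%d", 1:(2 * p_per)),
                      sprintf("s%d", 1:(2 * n_per)))
  X
}

test_that("consensus clustering is exact on well-separated blocks", {
  X <- two_block_matrix()
  cc <- consensus_cluster(X, 2, n_runs = 20, seed = 3)
  expect_equal(cc$cophenetic, 1.0)
  expect_gt(cc$silhouette_consensus, 0.95)
  expect_true(all(cc$consensus %in% c(0, 1)))
  expect_true(isSymmetric(cc$consensus))
  expect_equal(unname(diag(cc$consensus)), rep(1, ncol(X)))
  # the two blocks are exactly the two clusters
  expect_equal(length(unique(cc$labels[1:10])), 1)
  expect_equal(length(unique(cc$labels[11:20])), 1)
  expect_error(consensus_cluster(X, 2, n_runs = 1), "n_runs")
  expect_error(consensus_cluster(X, 50, n_runs = 5), "exceeds")
})

test_that("consensus is equivariant under sample permutation", {
  X <- two_block_matrix()
  perm <- c(15, 3, 8, 20, 1, 11, 6, 18, 2, 13, 9, 17, 4, 12, 7, 19, 5, 14, 10, 16)
  cc1 <- consensus_cluster(X, 2, n_runs = 10, seed = 5)
  cc2 <- consensus_cluster(X[, perm], 2, n_runs = 10, seed = 5)
  expect_equal(cc2$consensus, cc1$consensus[perm, perm], tolerance = 1e-12)
})

test_that("rank selection tabulates every candidate and handles pure noise", {
  X <- two_block_matrix()
  rs <- suppressWarnings(select_rank(X, k_range = 2:4, n_runs = 8, seed = 2))
  expect_equal(nrow(rs$metrics), 3)
  expect_equal(rs$metrics$rss_drop[-1],
               -diff(rs$metrics$rss), tolerance = 1e-12)
  expect_equal(rs$chosen_rank, 2)

  set.seed(12)
  noise <- matrix(stats::runif(30 * 24), 30, 24,
                  dimnames = list(sprintf("p%d", 1:30), sprintf("s%d", 1:24)))
  rs_n <- suppressWarnings(select_rank(noise, k_range = 2:4, n_runs = 6, seed = 4))
  expect_true(rs_n$chosen_rank %in% 2:4)   # no crash, a rank is returned
  expect_true(all(rs_n$metrics$cophenetic <= 1))
})

test_that("subtype renumbering follows the tau-profile convention", {
  X <- two_block_matrix()
  cc <- consensus_cluster(X, 2, n_runs = 10, seed = 5)
  rec <- data.frame(sample_id = colnames(X),
                    ptau181 = c(rep(10, 10), rep(40, 10)))
  out <- assign_subtypes(cc, rec)
  # two clusters, no k=3 tau rule: numbered by descending size (tie -> order)
  expect_setequal(out$subtype, 1:2)
  expect_equal(out$subtype, assign_subtypes(cc, rec)$subtype)  # deterministic

  # three clusters: highest-tau cluster must become subtype 2
  fx <- small_pipeline()
  fit <- suppressWarnings(
    csf_subtype(fx$z, fx$records, rank = 3, n_runs = 8, seed = 6))
  sub <- merge(fit$subtypes, fx$records[, c("sample_id", "ptau181")])
  mt <- tapply(sub$ptau181, sub$subtype, mean)
  expect_equal(unname(which.max(mt)), 2L)
  expect_equal(names(mt)[order(mt)], c("1", "3", "2"))
})

test_that("pipeline fit recovers planted subtypes on a separable cohort", {
  b <- generate_cohort(small_config(seed = 13L, effect_size = 2.5))
  fx <- preprocess_bundle(b)
  fit <- suppressWarnings(
    csf_subtype(fx$z, fx$records, rank = 3, n_runs = 10, seed = 2))
  sub <- merge(fit$subtypes, fx$records[, c("sample_id", "true_subtype")])
  expect_gte(adjusted_rand_index(sub$subtype, sub$true_subtype), 0.9)
  # our ARI agrees with an independent implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(adjusted_rand_index(sub$subtype, sub$true_subtype),
                 mclust::adjustedRandIndex(sub$subtype, sub$true_subtype),
                 tolerance = 1e-12)
  }
})
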