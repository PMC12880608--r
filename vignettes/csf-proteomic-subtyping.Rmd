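---
title: "Methods: CSF proteomic subtyping of Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF proteomic subtyping of Alzheimer's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Alzheimer's disease (AD) defined by abnormal amyloid biomarkers is clinically
and biologically heterogeneous. This package implements a complete pipeline
for discovering *biological subtypes* of AD from cerebrospinal-fluid (CSF)
proteomic profiles measured on an aptamer capture platform (relative
fluorescence units, RFU), characterizing the subtypes molecularly and
clinically, and testing whether they replicate in external cohorts. Because
the cohorts such analyses run on are access-controlled, the package also
ships a synthetic-cohort generator that plants known subtype structure, so
every stage of the pipeline is testable end to end.

# Pipeline overview

1. **A/T labelling** (`classify_at_framework`). A sample is a biologically
   defined case when CSF A&beta;42 falls below a cohort-specific amyloid
   cutoff (1098 pg/ml in the default, ADNI-style setting), irrespective of
   cognitive stage; a control when it is cognitively normal with
   A&beta;42 at or above the cutoff and p-tau181 at or below the tau cutoff
   (26.64 pg/ml default). Everything else — including records with missing
   biomarkers — is flagged `excluded` with a reason, never silently dropped.
   Cutoffs are arguments, never constants, because replication cohorts use
   different assays (e.g. 683/24 or 338/90 pg/ml).

2. **Analyte QC and aptamer collapse** (`filter_missingness`,
   `collapse_aptamers`). Analytes with a missing fraction *strictly* above
   10% are removed. Where several aptamers measure one protein, the one with
   the largest absolute mean log2 difference between the control and case
   groups is kept; exact ties resolve to the lexicographically first analyte
   id so results are platform-independent. Group means are computed on the
   log2 scale, consistent with the downstream transform.

3. **Normalization** (`normalize_to_controls`). Values are log2-transformed;
   residual missing entries are imputed with the per-protein cohort median
   (factorization and classifiers need complete matrices; the median is
   robust and scale-stable); each protein is then z-scored against the
   reference group — the biomarker-negative controls for discovery analyses,
   or the whole cohort (`reference_ids = NULL`) where a cohort-referenced
   scale is wanted. Positive values mean higher than reference. A protein
   with zero reference variance is an error naming the protein.

4. **Subtype discovery** (`csf_subtype`). Proteins separating cases from
   controls by Kruskal–Wallis at unadjusted p < 0.01 are retained (a screen
   feeding unsupervised clustering, not inference — hence no multiplicity
   correction), rescaled per protein to [0, 1] over the cases, and
   factorized by non-negative matrix factorization (NMF) with consensus
   clustering over 30 random restarts for each candidate rank k = 2..10.

5. **Characterization** (`differential_vs_control`, `fisher_enrichment`).
   Per protein, one least-squares model `protein ~ group + age + sex` with
   controls as the reference level gives each subtype's adjusted mean
   difference in z-units; Benjamini–Hochberg correction is applied within
   subtype across proteins. Significantly up- and down-regulated proteins
   are mapped to genes and tested separately for over-representation in
   user-supplied gene sets (GMT) by one-sided Fisher's exact tests against
   an explicit background universe, BH-corrected across sets.

6. **Clinical contrasts** (`fit_cox`, `schoenfeld_test`,
   `baseline_contrasts`, `longitudinal_slopes`). Progression to dementia is
   modelled by Cox regression (Efron ties) with subtype as a categorical
   predictor adjusted for age, sex, education and APOE &epsilon;4 carrier
   status, with all pairwise hazard ratios BH-corrected as one family.
   Proportional hazards are checked by correlating scaled Schoenfeld
   residuals with event-time rank. Baseline outcomes use OLS with the same
   covariates; longitudinal outcomes use linear mixed models
   `outcome ~ time × subtype + covariates` with subject-level random
   intercepts and slopes (REML).

7. **Replication transfer** (`train_transfer_model`, `predict_subtypes`,
   `predict()` on the fit). A random forest (500 trees) is trained on the
   discovery cases' z-scores restricted to the proteins shared with the
   replication platform, then applied frozen — no retraining — to the
   replication cohort, itself z-scored within its own cohort. Each sample
   gets the subtype with the highest predicted probability; exact ties go to
   the lowest subtype index and are flagged.

# The factorization and rank selection

The NMF core is the classic multiplicative-update algorithm for the
generalized Kullback–Leibler divergence D(X ‖ WH) — the default algorithm of
the widely used R implementation of NMF subtyping — written in compiled code
with an explicit objective trace. Choices that matter:

* **Initialization**: W and H uniform in (0, 1], one seed per restart
  (`seed + run index`), so runs are reproducible and independent.
* **Denominator floor**: 1e-12. Multiplicative updates leave exact zeros
  untouched, as is standard.
* **Stopping**: relative objective change below `tol` or `max_iter` sweeps.
  Single factorizations default to `max_iter = 500`, `tol = 1e-5`. The
  consensus stages default to `max_iter = 150`, `tol = 1e-4`: cluster
  memberships (arg-max of H) stabilize long before the divergence does, and
  on default-sized problems runs converge in well under 150 sweeps; the
  looser tolerance buys a several-fold speed-up of the rank scan without
  changing the consensus. The objective trace is non-increasing up to
  floating-point tolerance, and a non-converged run returns with a warning
  rather than an error.

**Consensus machinery.** Each restart labels samples by their dominant H
coefficient; the binary co-clustering matrices average into a consensus
matrix C. Stability is summarized by (i) the cophenetic correlation between
the dissimilarity 1 − C and the cophenetic distances of its average-linkage
hierarchy, (ii) the mean silhouette width of the k-group tree cut under
1 − C, and (iii) the squared Frobenius residual (RSS) of the best-objective
run. Final labels come from the consensus tree cut, not from any single run.

**Rank rule.** The textbook prescription — pick the k where cophenetic
correlation, silhouette and the RSS drop `rss(k−1) − rss(k)` all peak —
needs care when the clustering is strong: cophenetic correlation saturates
near 1 across several ranks and its exact arg-max becomes Monte-Carlo noise
of the restarts (a handful of borderline samples can form a stable
micro-cluster at k one above the truth, pushing cophenetic marginally
higher there). `select_rank` therefore treats cophenetic correlation and
silhouette as the estimates they are: each gets a delete-one-run jackknife
standard error, and ranks within two standard errors of a metric's maximum
count as tied for it. The chosen rank is the smallest k in the maximizing
tie set of all three criteria; if no k satisfies all three, the cophenetic
tie set is resolved by the largest RSS drop (smallest k when no drop is
defined), with a warning. The RSS drop is left undefined at the smallest
rank — anchoring it with a rank-1 fit was tried and rejected, since the
1 → 2 drop dominates in any clustered data. The full metric table (with
standard errors) is always returned so the user can override the choice.

**Subtype numbering.** Cluster indices from a factorization are arbitrary.
With three clusters and CSF p-tau181 available, the package renumbers so
the cluster with the *highest* mean p-tau181 becomes subtype 2 and the
remaining two are numbered 1 and 3 by ascending mean p-tau181. This mirrors
the tau profile of the subtypes this pipeline targets — the
intermediate-severity, tau-highest group is conventionally "subtype 2",
the mildest group "subtype 1", and the fastest-progressing group, with
intermediate tau, "subtype 3" — and makes numbering comparable between
discovery and replication. For other k, or without p-tau, clusters are
numbered by descending size. The rule is deterministic given the fit.

# The synthetic cohort generator

`generate_cohort` draws the study conditions the pipeline assumes:

* **Design**: 85 biomarker-negative controls and 465 cases in three latent
  subtypes of 97/200/168 — the structure of the discovery cohort this
  pipeline targets. Case A&beta;42, p-tau181 and t-tau means and spreads
  are taken from that cohort's clinical table (p-tau181 means
  15.51/39.42/32.16 pg/ml, so subtype 2 is tau-highest and subtype 3
  intermediate); amyloid is truncated at the 1098 pg/ml cutoff on the
  appropriate side so A/T labelling is deterministic.
* **Proteomics**: 200 proteins with baseline log2-RFU means uniform in
  [8, 12]; 25 informative proteins per subtype (disjoint sets), shifted by
  `effect_size` (default 1.5) times `noise_sd` (default 1) z-units in that
  subtype only, with signs alternating across proteins; values are
  exponentiated to pseudo-RFU so the log2 step is genuinely exercised. 5%
  of proteins carry a second, signal-attenuated aptamer (exercising the
  collapse step) and 2% of non-informative analytes receive 15% missing
  entries (exercising the 10% QC filter without touching planted truth).
  200 proteins keeps a full rank scan with 30 restarts affordable on one
  CPU while leaving the screen, factorization and transfer non-trivial;
  the informative fraction (37%) is of the order seen in the real screen
  (590 of 6361).
* **Outcomes**: conversion to dementia is exponential with subtype hazards
  0.05/0.10/0.20 events/year (ordering as observed: subtype 3 fastest,
  subtype 1 slowest; magnitudes are free parameters, not published values),
  censored at 10 years; baseline-demented cases are excluded from the risk
  set. Cognition follows subject-level random intercepts/slopes around
  subtype mean slopes (−0.3/−0.6/−1.2 points/year; MMSE-like scale) with
  annual visits. Covariates (age, sex, education, APOE &epsilon;4 count)
  are drawn independently of subtype by default so adjusted and unadjusted
  contrasts agree in tests.
* **Replication** (`derive_replication`): a fresh draw from the *same*
  latent model, keeping a random 80% of proteins and applying a per-analyte
  gain (2^U(−1,1)) plus a small positive offset to emulate a platform
  shift. Per-cohort z-scoring removes the gain exactly, the offset only
  approximately — which is the point.

What the generator does **not** emulate: aptamer chemistry and vendor
normalization (upstream of delivered data), correlated protein modules
(proteins are independent given subtype), non-exponential hazards,
informative dropout, batch effects, or covariate–subtype confounding
(available as a switch-off default only in the sense that covariates are
independent; there is no confounding generator). Tests passing on this
generator therefore demonstrate that the machinery is correct and
calibrated under the declared model — not that real CSF data satisfy that
model.

# Statistical conventions and numerical details

* **FDR scope**: per-protein contrasts are BH-corrected within subtype
  across proteins; enrichment across sets; clinical pairwise contrasts as a
  family of three per outcome. Families are never pooled across unrelated
  outcome types.
* **Kruskal–Wallis degenerate input**: a protein constant across samples has
  no rank information; it is assigned p = 1 and dropped, not an error.
* **Unit-interval scaling**: a constant protein maps to all zeros.
* **Linear models**: all proteins share one design matrix, so the
  differential fit is a single QR decomposition; rank deficiency is an
  error naming the collinear column.
* **Cox models**: Efron tie handling (visit grids produce ties); a subtype
  with no events is reported as separation rather than returning an
  unstable estimate.
* **Mixed models**: REML with random intercept and slope; on convergence
  failure the model falls back to random intercepts only with a warning.
  Pairwise slope contrasts use Satterthwaite degrees of freedom.
* **APOE coding**: carrier / non-carrier (derived from allele count when
  needed), not allele dose.
* **Transfer z-scores**: both sides are z-scored within their own cohort by
  default (the reference group for classifier features is a convention; the
  control-referenced variant is available by passing `reference_ids`).
  Missing panel proteins at prediction are a hard error — restriction to
  the shared panel happens at training, never by silent imputation.
* **Cophenetic edge case**: a consensus matrix with zero distance variance
  (perfect agreement) is defined to have cophenetic correlation 1.

# Problem sizes used by the shipped checks

The test suite and the acceptance script regenerate everything from code:
module tests run on a 145-sample, 80-protein cohort; the full-scale checks
use the default 550-sample, 200-protein cohort with a complete k = 2..10
scan at 30 restarts (about half a minute per fit), ten independent seeds
for rank recovery, 200 replicates for Schoenfeld calibration, and
simulation sizes of a few hundred subjects for the Cox and mixed-model
recovery checks. These sizes are the package's choice of a
desk-scale experiment that still has the statistical resolution the
properties require.

# Known limitations

* The composite rank rule is a heuristic; on weakly separated data the
  three criteria can legitimately disagree, and the emitted metric table —
  not the single chosen rank — is the result to report.
* Consensus clustering cost grows with rank range × restarts × matrix
  size; thousands of proteins with hundreds of samples are feasible, but
  the jackknife adds one hierarchy per restart per rank.
* The per-protein linear model assumes homoscedastic Gaussian residuals on
  the z-score scale; heavy-tailed proteins are screened by a rank test but
  characterized by a mean model.
* Random-forest transfer assumes the shared panel carries the subtype
  signal; with very few shared proteins the model warns but proceeds.
* The generator's independence assumptions (proteins, covariates) make
  power estimates optimistic relative to correlated real data.
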