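# csfsubtyper

Biological subtyping of Alzheimer's disease (AD) from cerebrospinal-fluid
(CSF) proteomics, as an end-to-end, tested R pipeline.

## The problem

Amyloid-defined AD (CSF Aβ42 below a cohort-specific cutoff) is biologically
heterogeneous. Given a samples × proteins abundance matrix from an aptamer
platform (relative fluorescence units), sample biomarkers and longitudinal
clinical follow-up, this package:

1. labels cases and controls under the **A/T framework**
   (case: Aβ42 < cutoff; control: cognitively normal, Aβ42 ≥ cutoff and
   p-tau181 ≤ cutoff);
2. performs analyte QC (strict 10% missingness filter), collapses multiple
   aptamers per protein to the most case/control-discriminating one,
   log2-transforms and z-scores against the control group;
3. screens for case-associated proteins (Kruskal–Wallis, p < 0.01,
   uncorrected), rescales them to [0, 1], and clusters the cases by
   **non-negative matrix factorization** X ≈ WH (multiplicative updates for
   the generalized Kullback–Leibler divergence D(X ‖ WH)) with consensus
   over 30 random restarts; the rank k = 2..10 is chosen where **cophenetic
   correlation**, **silhouette consensus** and the **RSS drop**
   rss(k−1) − rss(k) jointly peak (tie sets use jackknife standard errors
   of the consensus metrics);
4. characterizes each subtype by covariate-adjusted per-protein linear
   models against controls (BH-FDR within subtype), splits signatures into
   up/down gene lists, and runs one-sided Fisher's-exact
   over-representation against a declared gene universe;
5. contrasts clinical progression between subtypes: Cox proportional
   hazards for conversion to dementia (Efron ties; Schoenfeld diagnostics),
   baseline linear models, and linear mixed models with random intercepts
   and slopes for longitudinal decline;
6. **transfers** the subtypes to replication cohorts: a random forest
   trained on discovery z-scores restricted to the shared protein panel is
   applied frozen, assigning each replication sample the subtype with the
   highest predicted probability.

Real cohorts of this kind are access-controlled, so the package includes a
synthetic-cohort generator (`generate_cohort`) that plants known subtype
structure — 85 controls + 97/200/168 cases, subtype-specific protein
signatures, subtype-graded dementia hazards and cognitive slopes, and a tau
profile with subtype 2 highest — so the whole pipeline is testable without
any data access. See the methods vignette
(`vignettes/csf-proteomic-subtyping.Rmd`) for the model, conventions and
limitations.

## Worked example

```r
library(csfsubtyper)

cfg    <- cohort_config(seed = 1)          # default study conditions
bundle <- generate_cohort(cfg)

rec  <- classify_at_framework(bundle$metadata, cfg$abeta_cutoff, cfg$ptau_cutoff)
ctrl <- rec$sample_id[rec$at_label == "control"]
ad   <- rec$sample_id[rec$at_label == "AD"]

pm <- filter_missingness(bundle$proteomics)          # strict 10% rule
pm <- collapse_aptamers(pm, ctrl, ad)                # one aptamer per protein
z  <- normalize_to_controls(pm, reference_ids = ctrl)

fit <- csf_subtype(z, rec, k_range = 2:10, n_runs = 30, seed = 2)
fit
```

```
<csf_subtype> 59 proteins screened in, rank 3
  cophenetic 0.997, silhouette 0.949, RSS 540.4
  subtype sizes: 97/200/168
```

59 proteins pass the case/control screen; the consensus metrics peak at
rank 3, and the three recovered subtypes have sizes 97/200/168 — exactly
the planted partition (adjusted Rand index 1.0). Subtypes are numbered by
the tau convention: subtype 2 is the p-tau-highest cluster. Downstream:

```r
rec$subtype <- fit$subtypes$subtype[match(rec$sample_id, fit$subtypes$sample_id)]

cx <- fit_cox(bundle$survival, rec)        # progression to dementia
cx$contrasts[, c("contrast", "hr", "p", "q")]
```

```
  contrast       hr            p            q
1  s2 - s1 1.984342 1.424807e-03 1.424807e-03
2  s3 - s1 4.905529 8.478214e-14 2.543464e-13
3  s3 - s2 2.472119 1.225457e-09 1.838185e-09
```

The hazard ordering (subtype 3 fastest, subtype 1 slowest) matches the
planted rates 0.05/0.10/0.20 events/year (true ratios 2 and 4). A
replication cohort on an 80%-shared, platform-shifted panel is assigned by
the frozen classifier with `predict(fit, replication_z)`; on the default
generator the agreement with the planted labels is ≈ 0.99 and the predicted
subtype 2 again shows the highest mean p-tau.

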