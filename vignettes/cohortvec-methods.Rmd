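---
title: "Patient embeddings from coded EHR histories: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient embeddings from coded EHR histories: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cohortvec)
```

## The problem

A patient's coded electronic health record is a sparse, irregular sequence of
diagnosis (ICD-9/ICD-10) and procedure (CPT-4) codes stamped with the
patient's age. `cohortvec` turns such histories into fixed-length numeric
vectors -- one 50-dimensional vector per patient-year and their arithmetic
mean per patient -- and provides the downstream analyses those vectors are
meant to power: phenome-wide disease-state classification and onset
prediction, bulk phenotyping, comorbidity subtyping within a phenotype,
survival contrasts between subtypes, and post-onset progression analysis.

The representation is built in three stages.

1. **Vocabulary embedding (VAE).** Every code that occurs more than five
   times is kept; each retained code is described by its occurrence profile
   over patient-age weeks 0--4320 (90 years). A variational autoencoder with
   a three-layer encoder compresses each profile to a 50-dimensional latent
   mean. Besides the reconstruction and KL terms, a cosine-structure loss
   penalises distortion of pairwise cosine similarities between codes, so
   linear correlation structure in the raw profiles survives compression.
2. **Year-sentence transformer.** All of a patient's codes within one
   age-year form an unordered "sentence" (padded to length 250). An
   encoder-decoder transformer -- with *no positional encodings anywhere*,
   because within-year code order in an EHR is administrative, not clinical
   -- is trained to predict the next year's sentence from the current one,
   with 20% of input codes masked. The per-year patient representation is
   the mean over non-PAD positions of the final encoder states.
3. **Siamese fine-tuning.** A shared feed-forward tower (pre-embedding layer
   followed by a 50-dimensional embedding layer) is trained on pairs of
   pooled year vectors with two objectives: a contrastive distance loss on
   *is_same_patient* and a binary head on *is_next_event* (is the second
   vector the immediately following year of the first). Patient-level
   vectors are the exact arithmetic mean of the per-year vectors.

## Model parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_occurrences` | 5 | strict occurrence floor for vocabulary codes |
| `n_weeks` | 4320 | age-week bins of the code frequency matrix (90 years) |
| VAE `latent_dim` | 50 | code embedding width |
| VAE `hidden` | 1024, 256 | encoder widths (mirrored decoder) |
| VAE learning rate | 1e-7 | production preset; desk preset 1e-3 |
| Transformer L/H/dff/d | 6/10/2048/50 | layers, heads, FFN width, model width |
| `max_len` | 250 | year-sentence length cap |
| `mask_fraction` | 0.2 | input masking rate |
| Adam (transformer) | beta2 = 0.98, eps = 1e-9 | schedule reaches 0.002 at step 10,000 |
| Siamese lr / steps | 3e-4 / 5000 | fine-tuning schedule |
| `train_fraction` | 0.8 | classifier split (patient-grouped) |
| GMM `k_range` | 2--8 | BIC-searched component numbers |
| Enrichment `alpha` | 2e-5 | significance level on adjusted p |

The production VAE learning rate of 1e-7 is kept as the faithful preset; it
is far too slow for desk-scale matrices, so `vae_desk_config()` uses 1e-3.
The desk transformer preset (`transformer_desk_config()`: L = 2, H = 2,
dff = 64, d = 32, max_len = 32) preserves the architecture shape at a size
a single CPU trains in minutes.

Some details are under-determined by the three-stage description above and
were fixed as package conventions:

* **Frequency-row normalisation.** Raw code counts span orders of magnitude,
  so each code's frequency row is scaled to unit L2 norm before the VAE;
  reconstruction targets the normalised row. This makes the reconstruction
  and cosine losses commensurate.
* **Loss weights.** Total VAE loss = recon + 1.0 x cosine + 0.1 x KL,
  exposed in `vae_config()`.
* **Learning-rate schedule.** Linear warmup then inverse-square-root decay,
  calibrated so the rate at step 10,000 equals the configured target
  (0.002 in the production preset).
* **Encoder-decoder realisation.** The next-year objective is realised as
  an encoder-decoder transformer with teacher forcing on target-year
  tokens. Because neither encoder nor decoder has positional encodings, the
  decoder's causal self-attention sees only the *set* of previously emitted
  tokens; the deterministic age-then-code order within a sentence gives
  teacher forcing a well-defined target sequence without giving the model
  positional semantics.
* **Reserved tokens.** PAD, MASK and a decoder BOS are reserved ahead of
  the code vocabulary; they have no frequency profile, so they start as
  zero embeddings and are learned (like all code embeddings) during
  transformer training.
* **"Next year" adjacency.** Year binning is by patient age-year
  (`floor(age_days/365.25)`); pairs require consecutive age-years, and gap
  years break pairs.
* **Siamese negatives.** The same-patient objective as stated only pulls
  positives together; a margin hinge on negatives is required or the map
  collapses to a constant. The margin defaults to the median
  different-patient input distance, i.e. it is calibrated to the scale of
  the data rather than fixed in units the pooled space does not have.
* **Residual tower.** When the tower input width equals the embedding
  width, the tower is residual (`x + f(x)`) on standardised inputs, so
  fine-tuning perturbs the pre-trained geometry instead of replacing it
  with a random projection. Without this the clustering structure of the
  embedding space depended erratically on the number of fine-tuning steps.
* **Same-patient decision rule.** Distance is turned into a binary call by
  a threshold chosen to maximise accuracy on a held-in calibration half of
  the evaluation pairs; both pair tasks are scored on class-balanced pair
  subsets so chance is 0.5.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so `generate_cohort()`
draws cohorts in which every quantity the downstream analyses estimate is
planted and known:

* **Follow-up and density.** Follow-up years ~ 1 + Poisson(mean - 1),
  truncated at a maximum; newly drawn background codes per year ~ Poisson.
* **Heavy-tailed, age-structured code usage.** Background codes are drawn
  from a Zipf popularity distribution (so the minimum-occurrence vocabulary
  filter is exercised) weighted by a per-code Gaussian age profile (so the
  VAE's input has age structure).
* **Episodes of care.** A background code recurs in the following year with
  probability `bg_persist_prob` (default 0.5). This temporal autocorrelation
  is what makes *is_next_event* learnable: consecutive years of a patient
  share ongoing conditions, distant years do not. Without it, adjacent and
  distant years of a patient are exchangeable and the task is undecidable
  in principle. A consequence is that realised codes per year average
  roughly `(1 + bg_persist_prob) x codes_per_year_mean` plus signature and
  disease codes.
* **Identity signatures.** Each patient carries a few personal signature
  codes present in at least 90% of their years, powering *is_same_patient*.
* **Planted disease subtypes.** Each patient belongs to one latent subtype.
  An index-disease onset age is drawn from the subtype's Normal
  distribution; draws outside the observation window make the patient a
  true control with no disease process. Cases receive an index diagnosis
  code at onset (recurring thereafter), accrue their subtype's disjoint
  comorbidity phecode set with probability 0.9 per phecode per year, and
  this accrual starts a short prodromal window (default 2 years) before
  clinical onset -- the realistic mechanism by which the onset-prediction
  task (classifying the year *before* first diagnosis) has signal.
  Index-disease codes are excluded from the background draw: the index
  disease only arises from the planted process, so case/control labels are
  exact.
* **Mortality.** Post-onset survival is exponential with a per-subtype
  hazard; death truncates follow-up.

What the generator does *not* emulate: real code ontologies and their
hierarchies, visit-level clustering of codes, site- or era-specific coding
practice, demographic confounding (demographics are drawn independently of
subtype), informative censoring, and measurement error in ages. Passing
tests on these cohorts therefore demonstrates that the machinery recovers
planted structure of the stated kinds -- not that it would achieve any
particular performance on a real cohort.

## Downstream analyses

* **Classification tasks (per phenotype).** Disease-state: post-onset
  patient-years vs the same cases' pre-onset years. Onset prediction: the
  embedding at year onset-1 vs year-frequency-matched embeddings of
  never-affected patients (the pre-onset-years alternative is available as
  `negatives = "preonset"`). Bulk phenotyping: mean patient vectors vs
  ever-present labels. All use plain logistic regression on the embedding
  coordinates, an 80/20 split stratified by class and grouped by patient
  (no patient on both sides), and report AUROC and AUPRC. Phenotypes with
  fewer than `min_cases` (default 20) eligible cases are skipped with a
  logged reason.
* **Comorbidity subtyping.** Gaussian mixtures over `k_range` components,
  the number chosen by BIC (reported in the minimise convention
  -2 log L + k log n). Covariance structures are tried from full to
  spherical and BIC arbitrates, so high-dimensional fits fall back
  gracefully. The pipeline clusters the index-disease cases' mean vectors
  after centring and L2 row normalisation: patient means live on rays
  whose length encodes the fraction of follow-up spent post-onset (a
  nuisance), while the direction encodes the comorbidity mix; the
  directional (cosine) geometry is the appropriate one for such embedding
  vectors. `fit_gmm_bic()` itself applies no normalisation.
* **Enrichment.** Per (cluster, phecode), logistic regression of phenotype
  presence on a one-vs-rest cluster indicator adjusted for age of onset,
  gender, ethnicity, race and site (categorical covariates one-hot encoded
  with the largest level as reference; missing values become an explicit
  "unknown" level). The cluster coefficient is the log odds ratio;
  Benjamini-Hochberg adjustment across all tests with significance at
  adjusted p < 2e-5 (a Bonferroni switch is provided, as the two
  conventions both appear in practice). Completely separated fits are
  refitted with a small ridge and flagged; nothing is silently dropped.
* **Survival.** Kaplan-Meier curves per cluster, administratively censored
  at a 10-year horizon, with the global and all pairwise log-rank tests
  (pairwise BH-adjusted). Time zero is index-phenotype onset.
* **Progression.** Patients with an embedded year for all 10 post-onset
  years are averaged over that window; PCA on the averages; per-PC type-II
  ANOVA on age of onset, demographics and cluster.
* **Emerging phenotypes.** A phecode is a gain for a patient when its first
  occurrence is strictly after index onset (phecodes also seen at or before
  onset never count). Per-cluster gain frequencies, top-15 flagged with a
  deterministic tie-break (frequency descending, then phecode ascending).

## Numerical choices and degenerate inputs

* One year = 365.25 days everywhere; week = 7 days; ages beyond the last
  frequency-matrix week are clipped into it with a warning.
* Masking count is `ceiling(fraction x true_length)`, so a one-token
  sentence is fully masked; PAD positions are never maskable.
* Sentences longer than `max_len` keep their earliest tokens.
* The logistic classifiers are unpenalised; enrichment falls back to a
  small-ridge IRLS fit only under complete separation.
* All-PAD sentences cannot be pooled (error); empty embedding series cannot
  be averaged (error); single-class pair sets and single-class labels are
  rejected rather than scored.
* Every stochastic entry point takes an explicit integer seed, and the
  pipeline derives per-stage seeds from its global seed so stages are
  independently reproducible.

## Problem sizes

The desk-scale pipeline default simulates 400 patients (three subtypes,
150-code vocabulary, ~12-year follow-up), trains the VAE for 15 epochs, the
transformer for 1,200 steps and the siamese tower for 3,000 steps. These
sizes were chosen once so that index-case counts (~200) support a stable
mixture fit and 80/20 evaluation while the whole pipeline completes in a
few minutes on one CPU; the learnability oracle (copy task) uses the
desk-preset transformer for 2,000 steps. The neural components are
authored on a compact reverse-mode autodiff engine included in the package
(dense layers, layer normalisation, fused multi-head attention and fused
losses), whose gradients are verified against finite differences in the
test suite.

## Known limitations

* The transformer's sequence-recovery and masked-accuracy ceilings at desk
  scale are far below what a production run on a large cohort could reach;
  tests assert learnability and wiring, not production performance.
* The fine-tuning objective emphasises patient identity; in cohorts where
  identity signatures are orthogonal to subtype structure this can dilute
  cluster geometry, which is why the pipeline's clustering quality is
  asserted on the planted-subtype recovery (ARI) rather than on any fixed
  cluster count.
* `evaluate_pair_tasks()` scores balanced pair subsets; accuracies are not
  comparable to unbalanced-prevalence settings.
* The generator's distributions are conventions chosen for realism at desk
  scale, not estimates fitted to any real cohort.

## A note on training depth and representation quality

The next-year objective and the downstream stratification pull in
different directions. Training the transformer longer or hotter keeps
improving token prediction, but the final encoder states increasingly
encode prediction-specific features at the expense of the plain
code-identity information that pooled year vectors need for clustering
and classification. The desk preset therefore uses its faster schedule
(peak 3e-3, warmup 100) where the goal is to verify that the objective is
learnable, while the pipeline preset trains its transformer with a
gentler schedule (peak 2e-3, warmup 200, 1,200 steps) where the goal is
representation quality. Practitioners adapting the pipeline should treat
the transformer stage as pre-training to be stopped early, not trained to
convergence.
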