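---
title: "Models and methods behind phenostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenostrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenostrat)
```

phenostrat stratifies a diabetes cohort from its electronic health record
(EHR) layers — free-text clinical notes, assigned ICD-10 diagnoses,
longitudinal laboratory series and prescriptions — into groups of patients
with shared comorbidity and symptom profiles, and scores each patient's
glycemic dysregulation. This vignette explains the models, the parameters
that matter, the numerical choices, and what the bundled synthetic cohort
can and cannot tell you about behaviour on real clinical data.

## Dictionary tagging of clinical notes

Clinical narratives carry most of the symptom signal that assigned codes
miss, but at clinic scale a full NLP stack is neither necessary nor
auditable. `tag_corpus()` therefore implements dictionary NER: tokens are
lowercased, punctuation-stripped and passed through an optional lemma
table; dictionary terms (ICD-10 level-3 descriptions and a custom clinic
vocabulary, both as plain `term → code` tables) are matched over token
windows, longest term first.

Three behaviours deserve explanation:

* **Fuzzy matching.** Unmatched tokens may match a dictionary token within
  one Levenshtein edit (substitution, insertion or deletion), so the common
  clinical typo class — `diabtes` for `diabetes` — resolves correctly. We
  use Levenshtein rather than Hamming distance deliberately: dropped
  characters are the dominant typo type, and Hamming distance cannot
  express them. Tokens of three characters or fewer never fuzzy-match;
  at that length a single edit reaches too many unrelated words.
  A blocklist of rejected `(variant, code)` pairs stands in for the manual
  curation a clinic would do on fuzzy variants.
* **Negation and subject suppression.** A mention is flagged negated when a
  negation cue (*no, not, without, denies, ...*) or a non-patient subject
  cue (*mother, father, family, ...*) occurs within five tokens before it
  in the same sentence. The window, the cue lists and the sentence
  delimiters are all configurable; five tokens within a sentence is a
  conservative default for the short, telegraphic sentences typical of
  clinic notes. Negated mentions stay visible in the mention stream but are
  excluded from the code events used downstream.
* **Duplicate collapse.** When two vocabularies map the same surface term
  to the same code, one locus yields one mention.

## From code events to BM25 phenotype vectors

Assigned and text-mined code events are pooled per patient into frequency
lists. Uncomplicated primary diabetes codes (E10, E109, E11, E119) are
removed first: in a diabetes cohort they are near-universal and would
dominate every similarity, while the clinically interesting structure lives
in comorbidities, complications and symptoms. A patient whose every event
is excluded is kept, flagged, with an empty vector.

Frequencies are weighted with BM25, the classical probabilistic retrieval
scheme: the weight of code $c$ in patient $p$ is

$$\mathrm{IDF}(c)\cdot
  \frac{f(c,p)\,(k_1+1)}{f(c,p) + k_1\left(1 - b + b\,|p|/|p_{ave}|\right)},
  \qquad
  \mathrm{IDF}(c) = \ln\frac{N - n(c) + 0.5}{n(c) + 0.5},$$

with $f(c,p)$ the per-patient code frequency, $|p|$ the patient's total
event count (with multiplicity), $|p_{ave}|$ its corpus mean, $N$ the
number of patients and $n(c)$ the number of patients carrying $c$.
Defaults $b = 0.75$ (document-length normalization) and $k_1 = 1.2$
(frequency saturation) are the standard retrieval settings. Three
documented conventions: the constant in the length-normalization term is 1
(canonical BM25); the logarithm is natural (the base rescales all weights
uniformly and cancels in cosine similarity); and mined and assigned
duplicates of a code on the same day both count toward $f$, since repeated
documentation is itself signal. Codes carried by more than half the corpus
get negative weights — allowed, and sensible: sharing a near-universal code
is evidence against similarity.

## Patient similarity network and Markov clustering

Pairwise cosine similarities of the BM25 vectors below 0.5 are discarded;
the survivors are mapped affinely from $[0.5, 1]$ to $[10, 100]$
($w = 10 + 180(s - 0.5)$, the unique affine map between those intervals),
which stretches the dynamic range the clustering sees. The network is then
partitioned with Markov clustering (MCL): the column-stochastic transition
matrix is alternately squared (expansion) and taken to an entrywise power
with renormalization (inflation) until it stops changing; clusters are read
off the attractors. Inflation 1.2 gives the coarse granularity appropriate
when downstream analyses need clusters of 50+ patients.

Numerical choices, all exposed as arguments: self-loops are added per node
with the node's maximum incident weight (1 for isolated nodes) so the walk
is lazy and the iteration converges; entries below $10^{-10}$ are pruned to
keep the matrix sparse; convergence is declared when the maximum absolute
matrix change drops below $10^{-8}$, with a 200-iteration cap that raises a
diagnostic error rather than returning a half-converged partition.
Extraction is deterministic: attractors (positive diagonal mass) that share
an attracted node are merged; every node joins the merged cluster of its
highest-mass attractor, ties broken by lowest label; unattracted nodes
become singletons. Clusters of ten or fewer patients are dropped from the
*retained* view, and analyses that need statistical power use the
*analysis* view of clusters with at least 50 patients. Both thresholds are
arguments, since the size floor is a power decision, not a modelling one.

## Stability of the clustering

`stability_curve()` quantifies how much the partition depends on
individual edges. Two perturbations: *dilution* deletes each edge
independently with probability $\alpha$; *shuffling* applies
degree-preserving double-edge swaps to a fraction $\alpha$ of edges, so
every node keeps its degree and the edge count is unchanged (weights
travel with the rewired edges). Each perturbed network is re-clustered and
compared to the reference partition with the Variation of Information,

$$\mathrm{VI}(P, Q) = H(P) + H(Q) - 2I(P;Q),$$

reported in nats (the log base cancels against reference lines computed in
the same base). VI is a true metric on partitions, which makes curves
comparable across perturbation modes. As orientation, the curve carries
reference lines: the mean VI produced by randomly reassigning 10% and 20%
of vertices to different clusters. Nodes dropped by size filtering are
scored by restricting both partitions to the common node set — the only
well-defined comparison.

## Symptom groups

Clusters of the analysis view are summarised by the fraction of their
patients carrying at least one code in each ICD-10 chapter XVIII level-1
symptom block (R00–R09 through R95–R99). Patient-level presence fractions,
rather than raw code counts, keep the profile insensitive to
documentation volume. Profiles are grouped by agglomerative clustering
with Euclidean distance and classical Ward linkage (`ward.D`, on
unsquared distances; `ward.D2` available), and the tree is cut into `k`
groups. `k` defaults to 7 but is a user decision — the tree, merge
heights and a Newick export are returned so the cut can be inspected
rather than trusted.

## Enrichment and comorbidity statistics

**Code enrichment per cluster** uses an upper-tail binomial test with a
stratum-corrected expected probability: the expectation for a cluster is
the sum over (sex × birth-decade) strata of the stratum's share in the
cluster times the code's corpus-wide prevalence in that stratum. This is
the simplest correction consistent with a binomial test; it asks "is this
code more common than this cluster's demographic mix predicts?". The
binomial approximates the underlying sum of stratum-specific Bernoulli
draws by a single draw at the weighted mean probability — adequate at the
cluster sizes analysed (50+). Results observed in fewer than 10 patients
are excluded before Benjamini–Hochberg adjustment (they are uninterpretable
at this scale, and removing them first preserves power).

**Metadata contrasts** (age, diabetes duration, any numeric field) test
each cluster against all remaining clustered patients with a two-sided
Wilcoxon rank-sum test, BH-adjusted across the family; degenerate cases
(singleton clusters, constant fields) report `NA` rather than failing.

**Prescription enrichment** runs a two-sided Fisher exact test per
(cluster, ATC level-3 class) on the analysis clusters, BH-adjusted, with
the odds-ratio direction reported.

**Comorbidity pairs**: for every unordered pair of codes carried by at
least 10 patients, a two-sided Fisher exact test on joint presence, the
expected co-occurrence $n_A n_B / N$, and the comorbidity score
$\mathrm{CS} = \log_2\!\big((n_{both} + s)/(\mathrm{expected} + s)\big)$
with smoothing $s = 1$ so empty cells stay finite. Bonferroni adjustment
across all pairs, significance at adjusted $p \le 0.01$.

**Temporal directionality** reduces each pair to first-occurrence order:
among patients carrying both codes on distinct first dates, the count with
A first is tested against a fair coin with the exact binomial sign test,
separately in each direction, each family Bonferroni-adjusted. This is the
only exact test determined by first-occurrence data; same-day ties are
excluded from the counts and reported. The mean signed lag (days)
accompanies each pair. When more pairs reach significance than can be
displayed, `top_pairs_by_unique_codes()` takes pairs in rank order until
the budget of 100 distinct codes would be exceeded. Pairs significant in
exactly one symptom group are reported by `group_unique_pairs()`, and
`lag_anova()` asks, per pair, whether the lag distribution differs across
symptom groups (one-way ANOVA over per-patient lags).

## Glycemic dysregulation

Five binary criteria are evaluated per patient; the score is their count
and a patient is called dysregulated at score ≥ 3 — the composite is
deliberately transparent so each criterion can be audited.

1–2. **Code criteria**: presence of the clinic's custom dysregulation code
(`sdcL03`) and of the hyperglycemia codes (R73, E89), over combined
assigned + mined events.

3. **Change points in HbA1c.** Series are first preprocessed: values
outside the biological range 15–184 mmol/mol removed, same-day duplicates
averaged, series split at gaps longer than 365 days (a follow-up
interruption, configurable), and only segments with ≥ 5 values spanning
≥ 90 days (the red-cell lifetime) retained. Each valid segment is analysed
under a Gaussian observation model with a conjugate Normal-Gamma prior and
a geometric (constant-hazard, default 0.1) prior on segment lengths.
Because the series is complete at analysis time we compute the exact
smoothed posterior over segment starts by a forward–backward recursion
over closed-form segment marginal likelihoods, rather than the filtered
online recursion the same model admits — the smoothed posterior is
strictly better calibrated in retrospect. The noise prior is centred on a
robust scale estimate, the median absolute deviation of successive
differences divided by $\sqrt 2$, which a level shift barely inflates
(variance-based estimates absorb the shift and blunt detection). A change
point is reported when the posterior probability of a segment start within
one index (pooled, matching the resolution at which positions are
meaningful) reaches 0.5 *and* the mean level difference between the
flanking stretches is at least 5 mmol/mol — a shift smaller than assay
noise is not clinically interesting even when statistically certain. Both
gates are configurable. Note an interaction worth knowing: for planted
shifts near the 5 mmol/mol floor, the sampling error of the estimated
shift, not the posterior, limits sensitivity; the detector's stated
operating point (≥ 90% detection within ±2 indices at shifts of twice the
noise SD, ≤ 10% false positives on constant series) applies to shifts that
also clear twice the magnitude floor.

4. **HbA1c level at onset.** A linear mixed model of HbA1c on time since
diabetes onset with a patient-level random intercept (random slope added
when patients typically have ≥ 4 measurements, with fallback on
convergence failure) predicts each patient's level at time zero; the
criterion flags predictions at or above 53 mmol/mol, the diabetes
diagnosis threshold. Patients with one measurement stay in the fit and
shrink toward the population mean; patients without an onset date are
non-evaluable (flag false, status recorded).

5. **Severity bins.** Valid measurements are binned at 48, 53 and
75 mmol/mol (below diagnosis, diagnosis band, elevated, critical —
clinical convention, configurable); the criterion flags patients with more
than half their measurements at or above 53 mmol/mol.

**Lab contrasts.** Panel tests measured on at least 75% of the corpus are
kept; a test failing a Shapiro–Wilk normality check (on a deterministic
subsample, only when all values are positive) is log-transformed; values
are standardized to mean 0, SD 1 per test. Group differences (for
clusters, symptom groups, or the dysregulated split — the grouping is an
argument) are tested jointly with a one-way MANOVA (Pillai) on per-patient
test means and per test with two-sample Kolmogorov–Smirnov against the
rest, Bonferroni-adjusted.

## The synthetic cohort

Real EHR corpora of this kind are person-sensitive and not shareable, so
the package ships a generator whose output has exactly the statistical
structure the pipeline assumes, with full ground truth. It plants: `k`
clusters with disjoint code profiles (each profile mixing comorbidity and
symptom-chapter codes, drawn per patient with probability 0.8 against a
background code rate); templated English-like note sentences embedding
dictionary terms, a configurable fraction negated and a fraction carrying
exactly one character edit; HbA1c trajectories as level-plus-noise with a
+15 mmol/mol jump for the planted dysregulated fraction, which also
receives elevated baselines, dysregulation/hyperglycemia codes and a
standardized mean shift on half the lab panel; and one signature ATC class
per cluster. Every planted mention, label, change point and flag is
returned, so recovery can be scored exactly.

Defaults were fixed once, before any end-to-end checks, at values a
simulation study in this field would call realistic: 600 patients in 6
clusters, 8 profile codes per cluster, background code rate 0.05, ~6
mentions per patient, 10% negation, 5% typos, 12 HbA1c points, 30%
dysregulated, lab effect size 1 SD. Two generator details matter for
interpreting the tests. First, a planted typo is re-drawn until it is at
least two edits from every other dictionary token, so each fuzzy variant
has a unique resolution — typo recall then measures the matcher, not
dictionary collisions. Second, note language is templated; the templates'
filler words are disjoint from the dictionary. Consequently the exact
precision/recall the tests demonstrate says the matcher is lossless *given
its model of text*; it says nothing about Danish morphology, abbreviation
ambiguity, long-range negation scope or OCR noise in real narratives.
Separability is likewise planted: with disjoint 8-code profiles the
cosine/MCL stage recovers clusters almost perfectly, which validates the
machinery, not the claim that real diabetes comorbidity space is this
cleanly separable. With fewer, larger clusters (lower code IDF contrast)
recovery degrades — the generator exposes exactly the knobs
(`profile_codes_per_cluster`, `background_code_rate`) to explore that.

Problem sizes used by the test-suite: the end-to-end recovery checks run
the 600-patient study cohort; stability curves and permutation-invariance
checks use a 300-patient, 6-cluster cohort, where each MCL solve is
sub-second; null error-rate simulations use 500 patients × 50 codes × 50
replicates. These sizes were chosen as the smallest at which the measured
quantities stabilize.

## Known limitations

* The NER has no real linguistic model: no morphology beyond the lemma
  table, no parsing, a fixed-window negation heuristic. It is meant as a
  transparent, testable stand-in for a clinic-grade tagger with the same
  interface.
* The stratified binomial enrichment corrects composition only through
  stratum-weighted expectations; a regression formulation (logistic with
  covariates) would handle continuous confounders but is out of scope.
* The directional test uses first occurrences only; recurrent events and
  surveillance bias (one diagnosis prompting a work-up that finds the
  other) are not modelled.
* The change-point model assumes piecewise-constant means with Gaussian
  noise; slow drifts are reported, if at all, as late change points.
* MCL granularity is controlled by a single inflation parameter; no
  automatic selection is attempted, and quality diagnostics beyond the
  stability curve are not implemented.
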