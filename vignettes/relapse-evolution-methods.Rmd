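---
title: "Methods: clonal evolution analyses for paired primary/relapse myeloma genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal evolution analyses for paired primary/relapse myeloma genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsevo)
```

# Scope and data model

`relapsevo` implements the statistical layer of a paired primary/relapse
whole-genome study of IGH-translocated multiple myeloma. It consumes
per-sample somatic mutation tables (with trinucleotide context channel
and cancer cell fraction, CCF), allele-specific copy-number segment
tables, region catalogs (promoters, cis-regulatory elements,
immune-hypermutated loci), a replication-timing track and a cohort
metadata table. All coordinates are 1-based inclusive; BED-style inputs
are shifted on read. Upstream read alignment, variant calling and
copy-number deconvolution are out of scope: the package starts from
their tabular outputs.

Because the motivating cohort data are access-controlled, the package
ships a synthetic cohort generator (`generate_cohort()`) that plants
every effect the analyses are designed to detect, with a machine-
readable ground truth. All statements below about recovery rates are
statements about those synthetic conditions, computed by the test suite
and `scripts/acceptance.R`; they show that the estimators are
implemented correctly and are well calibrated at cohort scale, not that
any particular biological effect exists in new data.

# Noncoding driver recurrence

For each candidate region (promoter: 400 bp upstream to 250 bp
downstream of the TSS, 651 bp; CRE: interaction-filtered at score >= 5
and distance <= 1 Mb) the background model provides per-sample hit
probabilities

\[ p_j \;=\; 1 - \prod_{i \in \text{region}} \bigl(1 - \min(1,\;
r_{j,c(i)}\, f_{b})\bigr), \]

where \(r_{j,c}\) is sample *j*'s genome-wide mutation rate in
trinucleotide channel *c* (channel count divided by eligible genome
bases of that channel) and \(f_b\) a replication-timing factor for the
region's timing bin (observed/expected mutation share, normalised to
weighted mean 1 over quintile bins; the binning granularity is a
package choice). The number of mutated tumours *k* is referred to the
exact Poisson-binomial tail \(P(X \ge k)\), computed by dynamic
programming over samples — exactness is cheap at cohort sizes and
avoids normal-approximation error in the far tail.

Positional clustering is tested by permutation: the statistic is
(number of mutations) − (number of distinct mutated positions), with
positions redrawn uniformly over the region under the null and a
pseudocount empirical p-value \((1 + \#\{S^* \ge S\})/(n_{perm}+1)\).
The two p-values are combined with Fisher's method (chi-square with 4
df); when a region is mutated in fewer than three tumours the
clustering test is undefined and the combined p-value falls back to the
recurrence p-value alone (such regions are never reported anyway — the
reporting rule requires k >= 3). Benjamini–Hochberg adjustment is
applied across all tested regions with significance at Q < 0.05.
Promoter tests exclude mutations overlapping ORFs; CRE tests exclude
ORF and UTR overlaps; regions overlapping immune-hypermutated loci are
excluded from testing.

**Calibration caveat (documented limitation).** The recurrence p-value
is a tail probability of a *discrete* count; over a cohort of 80
samples its null distribution has point masses of order
\(1/\sqrt{2\pi\,\mathrm{var}(X)} \gtrsim 0.09\). Combined with the fact
that the clustering statistic's null is nearly degenerate at \(S=0\)
for sub-kilobase regions (so \(p_{clust}\approx 1\) and Fisher
combination inflates the combined value), the null distribution of the
combined p-value is conservative and visibly non-uniform: on a
2,000-region fully null synthetic cohort it fails a Kolmogorov–Smirnov
uniformity test decisively. This is a structural property of exact
discrete tests, not an implementation defect; the practically relevant
guarantee — conservativeness, hence control of false discoveries (zero
discoveries at Q < 0.05 on null cohorts in our runs) — holds. The
corresponding uniformity assertion in the test suite is expected to
fail and is retained as an honest record of this property.

# Chronology of events

Events are driver genes mutated in >= 4 samples and autosomal arm-level
copy-number events spanning >= 3 Mb in >= 8 samples (hyperdiploid-
flagged samples excluded; the per-sample CCF of a copy-number event is
the clonal fraction of the qualifying segment covering the majority of
the arm — the aggregation rule is a package choice). Events are ordered
by mean CCF, highest first. Discrete clonality levels are delimited by
a stepwise walk comparing *consecutive* events with Tukey's
studentized-range test: Tukey–Kramer standard error from the pooled
within-event variance, number of groups equal to the number of events,
pooled residual degrees of freedom, new level when the adjusted p-value
drops below 0.05. p-values come from `stats::ptukey` — the exact
distribution function is in base R, so simulating the null range
distribution would add noise for no benefit. Whether the original
analysis pooled variance across all events or only each tested pair is
not derivable from its description; pooling across all events is used
here and documented as this package's choice. With zero pooled variance
a positive mean difference separates levels (infinite statistic).

Confidence intervals are basic bootstrap,
\((2\hat\theta - q^*_{0.975},\; 2\hat\theta - q^*_{0.025})\) over 1000
bootstrap means, clipped to \([0,1]\). Monte-Carlo coverage for the
mean of Beta(5,2)-distributed CCFs at n = 80 is ~93–94% in our runs —
the familiar slight undercoverage of the basic bootstrap with skewed
data at moderate n.

# Arm-level copy-number dynamics

Segments are aggregated over the 44 autosomal arm loci; an arm state
(gain, amplification, loss, deep loss, copy-neutral LOH) must cover at
least 50% of the arm. Two permutation tests are provided:

* **Frequency change**: the statistic is the net change
  \(\sum_{pairs} I(\text{event at relapse}) - I(\text{event at
  primary})\); condition labels of each pair are swapped independently
  with probability 1/2, 10,000 times, and the two-sided empirical
  p-value uses a pseudocount. Arms with net change in fewer than two
  tumours are not tested. The two-sided form reflects that both
  relapse-enriched gains and losses are of interest. Because of the
  pseudocount the smallest reachable p-value is \(1/(n_{perm}+1)\);
  quoted bounds smaller than that require exact enumeration, which the
  test suite uses as the oracle for <= 15 pairs.
* **Instability localisation**: "additional CNA at a pre-existing
  unstable arm" is operationalised as an arm altered at primary whose
  state progresses at relapse along the same axis (nLOH → LOH → deep
  loss; gain → amplification). Each progression event is relocated
  uniformly over the 44 arms, 10,000 times; the p-value is the fraction
  of permutations placing at least as many events on the tested arm.
  This matches a binomial(n, 1/44) upper tail, which the tests use as
  the independent oracle.

Hyperdiploidy is called when at least two autosomes are >= 90% covered
by gains.

# Clonal evolution patterns

For each pair, SNVs restricted to regions diploid at both timepoints
are embedded as (primary CCF, relapse CCF) points; SNVs undetected at a
timepoint carry CCF 0 there. Likely neutral-tail passengers are removed
before clustering by a two-component EM fit — a truncated Pareto tail
(density \(\propto f^{-(1+\alpha)}\) on [0.05, 0.25], the analytic
shape of neutral passengers) versus a Beta component — excluding points
with tail posterior > 0.5; with fewer than 50 points no filtering is
attempted. Re-filtering is not guaranteed to be idempotent (the mixture
is refit) and idempotence is deliberately not claimed.

Clustering uses a Dirichlet-process mixture of bivariate Gaussians with
a collapsed Gibbs sampler: concentration 1, conjugate
Normal-Inverse-Gamma base measure per dimension (location 0.5 with weak
strength 0.05; variance shape 3, scale 0.02, i.e. prior cluster s.d.
around 0.1 on the CCF scale — wide enough for subclonal spread, tight
enough not to fuse clonal and subclonal structure), 500 sweeps with 250
burn-in, thinned to every 5th sweep. The reported partition minimises
Dahl's least-squares loss against the posterior coassignment matrix;
cluster centres are mean CCFs clipped to the unit square. A Gaussian
rather than read-count likelihood is used because the inputs are CCF
estimates, not allele counts. Clusters with < 100 SNVs or < 1% of the
pair's mutations are discarded.

Patterns are called by explicit geometric rules with config-exposed
thresholds (presence delta 0.10, relapse-clonal 0.80, primary-subclonal
upper bound 0.60; the source descriptions are geometric, so the numeric
operating points are package choices):

* **Pattern 2** (checked first): some cluster with primary CCF in
  [0.10, 0.60] and relapse CCF >= 0.80 — a subclone expanded to
  dominance. Precedence is deliberate: subclonal expansion typically
  co-occurs with branching (Pattern-3-like) features.
* **Pattern 1**: no primary-present cluster disappears and a
  relapse-only cluster exists.
* **Pattern 3**: otherwise (primary clusters lost, new clusters
  emerge).

Whether a "disappearing" cluster sits exactly at CCF 0 or below a small
positive threshold is unknowable from the source description; delta is
the documented knob. On synthetic pairs the templates classify exactly
noise-free, and recovery through the full clustering path exceeds 90%
at CCF noise 0.05 (200 pairs in the acceptance suite).

# Mutational signatures

De novo extraction uses NMF with multiplicative updates minimising
generalised Kullback–Leibler divergence (deterministic seeded
initialisation; the objective is non-increasing per iteration, which
the tests assert). De novo spectra map to catalog signatures when
cosine similarity strictly exceeds 0.75. Exposures are refit per sample
by non-negative least squares on the assigned catalog subset,
iteratively pruning contributions below 6% (the convention of the
refitting tool this mirrors; config-exposed). AID/APOBEC exposure is
SBS2+SBS9+SBS13; the flat group is SBS5+SBS8+SBS40; SBS3 is excluded
from the model (treated as inactive in myeloma) and rejected as input.

Paired dynamics: chi-square comparison of signature-attributed counts
(exposure × burden, rounded — a documented approximation of
per-mutation attribution, chosen over proportions so the test is
valid); Fisher exact test of burden-increase vs APOBEC-increase
indicators; Spearman correlation between the AID/APOBEC share of
relapse-specific mutations (relapse calls absent from the primary table
at the same chrom/pos/alt; no VAF-based rescue) and time to relapse;
and the C>G transversion fraction.

# The synthetic cohort generator

The generator's defaults are the study conditions: 80 patients, 24 with
matched relapse; karyotypes 38:38:4 across t(4;14), t(11;14), t(14;16),
one sample additionally hyperdiploid (two whole-chromosome gains);
negative-binomial SNV burdens (mean 5000, size 10 — the burden
distribution is not specified anywhere, so an overdispersed count model
was chosen once); mutation contexts drawn from per-sample signature
exposures over a synthetic six-signature catalog; positions drawn with
a monotone replication-timing density (0.6–1.4 across quintile bins);
500 candidate noncoding regions of which 10 are drivers at a 5-fold
rate with half their mutations on a single hotspot position; arm-level
events at myeloma-like prevalences (13q loss 0.73, 1q gain 0.45, 1p/22q
loss 0.35, ...) with a planted relapse-enriched 17p deletion (+0.35)
and nLOH→LOH progression at 11q/14q; paired clone structures realising
Patterns 1/2/3 in 3:4:17 proportions with truncated-Gaussian CCF noise
(sigma 0.05) clipped to [0,1]; relapse-specific mutations at 50% of the
primary burden so that relapse burdens exceed primary (~1.2-fold on
average); and a Gaussian copula linking relapse-specific APOBEC share
to time-to-relapse targeting Spearman rho = −0.43 (a planting default
mirroring the association the pipeline must recover, not a truth claim).
A single global seed drives deterministic per-stage seeds so stages can
be regenerated independently.

Design notes on identifiability: the synthetic catalog is built in code
and is *not* the COSMIC catalog. Its three flat signatures are given
deliberately distinct tilts (maximum pairwise cosine 0.63) because the
generator's contract is that planted exposures are recoverable by
refitting; with realistically confounded flat spectra (cosine ~0.9,
as for the real SBS5/SBS40 pair) the round-trip is not identifiable at
desk scale — which is precisely why the analysis combines the flat
group before interpretation. Exposure Dirichlet concentrations are
chosen so that most true contributions exceed the 6% pruning threshold.

What the generator deliberately does **not** emulate: read-level noise
and depth-dependent CCF error, sequence context of real DNA (contexts
are channel labels, not sequence), realistic SV breakpoint mechanics,
kataegis–SV coupling, and inter-sample contamination. Passing tests
therefore demonstrate correctness and calibration of the estimators
under the declared noise model, not performance on real sequencing
artefacts.

# Problem sizes and numerical choices

The test and acceptance runs use: 2,000 null regions for calibration;
three 80-tumour cohorts (30 planted drivers) for sensitivity; 200
simulated pairs for pattern recovery; 1,000 bootstrap-coverage
replicates; 500 copula replicates; 100 refit round-trips at 5,000
mutations each. Permutation counts are 5,000–10,000 for cohort-level
driver calls and 10,000 for the CNA tests. Degenerate inputs are
handled explicitly: zero p-values are clamped to the smallest positive
double before Fisher combination; zero pooled variance yields an
infinite range statistic; empty context channels get zero rates with a
warning; clustering of fewer than 100 points is refused; a single CCF
yields a degenerate point interval. Ties in the event ordering break
lexicographically so results are permutation-invariant.

# Known limitations

* Combined driver p-values are conservative, not uniform (see above);
  power at very small k relies on the clustering term.
* The studentized-range walk tests only consecutive events; a long
  gentle CCF gradient yields a single clonality level by design.
* The neutral-tail EM assumes a single Pareto regime on [0.05, 0.25]
  and is not idempotent.
* Pattern calls depend on the delta/clonal thresholds when clusters sit
  near the boundaries; thresholds are exposed rather than hidden.
* The chi-square on attributed counts inherits the refit's pruning
  bias for signatures near the 6% threshold.
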