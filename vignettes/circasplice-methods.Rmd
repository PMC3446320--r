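---
title: "Methods: detecting circadian alternative splicing from probe-level exon arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting circadian alternative splicing from probe-level exon arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circasplice)
```

# The problem and the model

Exon arrays interrogate every exon of a gene with a small probeset (here 4
probes). A circadian change in *splicing* shows up as a sample-dependent
departure of one probeset from its gene's overall expression — which may
itself oscillate with far larger amplitude. The probe-model route separates
the two. Per transcript cluster, on quantile-normalized log2 intensities,
Tukey's median polish fits the additive RMA decomposition

$$\log_2 I_{ki} = m + c_i + p_k + r_{ki},$$

chip effects $c_i$ absorbing the gene's (possibly rhythmic)
transcript-level expression, probe effects $p_k$ absorbing affinity. The
FIRMA score of probeset $j$ in sample $i$ is
$F_{ji} = 2^{\mathrm{median}_{k \in j} r_{ki}}$: 1 means no departure, and a
splicing change restricted to one exon concentrates in exactly these
residuals. Because the polish is median-based, a departure in one of eight
probesets barely perturbs the gene fit (but see *Leakage* below).

The screen operates on $\log_2 F$: a per-probeset one-way ANOVA across the
circadian-time groups, with Benjamini–Hochberg FDR control at
$\alpha = 0.05$ over all tested probesets, then removal of probesets whose
scores differ between the antiphase pools $\{CT0, CT12\}$ and
$\{CT6, CT18\}$ (BH-adjusted over the same universe). A 24-hour sinusoid
sampled on this grid contributes identically to both pools for *any* phase
(the pool means cancel exactly), while a 12-hour rhythm alternates with the
pools, so this single contrast excludes ultradian probesets without fitting
any curve. With two pools the F and t formulations coincide ($F = t^2$); the
t form is implemented.

## Variance moderation

The default test is the empirical-Bayes moderated ANOVA. Residual variances
$s_g^2$ (df $= n - 4 = 8$ at the default design) are shrunk toward a scaled
inverse-chi-square prior fitted by method of moments on $\log s_g^2$:
the excess of the observed spread of log-variances over the theoretical
sampling spread ($\mathrm{trigamma}(df/2)$) determines $d_0$ through the
inverse trigamma, and
$\tilde s_g^2 = (d_0 s_0^2 + df\, s_g^2)/(d_0 + df)$, with the moderated F
referred to $df + d_0$ denominator degrees of freedom. Two numerical
choices:

* when the observed spread does not exceed the sampling spread, $d_0$ is
  infinite and all variances pool. The pooled value is the **geometric
  mean** of the observed variances — not the bias-corrected
  $\exp(\bar e)$ — so that exactly equal variances shrink to themselves and
  the moderated F then equals the plain F. This deviates from limma's
  infinite-prior constant by the factor $\exp(\psi(df/2) - \log(df/2))$;
  the finite-$d_0$ branch matches limma to numerical precision (and is
  tested against `limma::squeezeVar`).
* probesets with exactly zero within-group variance are flagged degenerate,
  excluded from the prior fit, and assigned $p = 0$ (separated means) or
  $p = 1$ (constant), never dropped silently.

## Phase metrics

No cosinor fitting: with four samples per cycle the discrete definitions are
the honest ones. Folds are taken versus the CT0 mean with the symmetric
signed convention ($\rho < 1 \mapsto -1/\rho$), acrophase is the sampled
time of the largest positive fold, amplitude the signed fold of largest
absolute value, ties breaking to the earliest time. Planted on-grid phases
are exactly recoverable under this estimator; that is why the generator
draws phases from the sampling grid by default (a continuous-phase mode
exists, under which exact recovery is not expected).

## SOTA clustering

Candidate profiles (replicate-mean $\log_2 F$ per CT, z-scored over times)
are clustered by a divisive self-organizing tree with correlation distance
$1 - r$. The growth step splits the cell of highest resource (mean
member-to-centroid distance); children are seeded deterministically on the
cell's two mutually most distant members, members re-assign to the nearer
child, and one training epoch adapts winner/parent/sibling centroids with
learning rates 0.01/0.005/0.001. Growth stops at $k$ cells (default 4).
Seeding children on extreme members rather than on perturbed copies of the
parent centroid is a deliberate choice: it makes the procedure fully
deterministic for a fixed input order and avoids the degenerate case where
the mean of antiphase z-scored profiles is a constant vector with undefined
correlation. Constant profiles are assigned distance 1 to everything.

# The synthetic world

`generate_dataset()` emulates: additive chip+probe structure on the log2
scale, a 24-h cosine transcript rhythm (log2 amplitude 1) in 30% of
clusters, an exon-restricted splice departure (log2 amplitude 0.5, the
stated effect size of the recovery benchmarks) in 5% of probesets, a 12-h
ultradian departure in a disjoint 5%, probe affinities $N(0, 1)$, and
log-normal measurement noise (Gaussian on log2, SD 0.2) at $n = 3$
replicates per CT $\in \{0, 6, 12, 18\}$. Default geometry is 125 clusters
× 8 probesets × 4 probes = 1000 probesets, matching the core-probeset
structure of a mouse exon array (genes average ~8 core exon-probesets of 4
probes). Planted-fraction counts use floor plus one seeded Bernoulli unit
for the remainder, keeping realized counts within 1 of
`round(frac * total)`.

What it does **not** emulate: optical background and its convolution model,
cross-hybridization, GC effects, probe outliers, or inter-array scale drift.
A green recovery test therefore establishes the statistical pipeline's
behaviour under the additive model it assumes, not robustness to array
artefacts. An optional modal-background subtraction mode exists only to
exercise the switch; it is off by default because the generator plants no
offset.

## Leakage

A splice departure is not perfectly confined to its probeset: the per-sample
chip-effect median over the cluster's probes shifts slightly (for 4 of 32
probes shifted by $\delta$, by roughly the $\delta$-weighted density ratio
at the median, ~0.03–0.06 log2 units here), imprinting a small *opposite*
rhythm on sibling probesets. This is intrinsic to the probe-model approach,
not an implementation artefact; it is the main source of false discoveries
in the recovery benchmarks and the reason the generator's cluster size
matters. With realistic 8-probeset clusters the planted-recovery benchmark
achieves sensitivity 1.0 at false-discovery proportion ≤ 0.1.

# QPCR arithmetic

Quantities are efficiency-corrected, $Q = E^{-C_t}$ (or taken as given in
relative-concentration mode), normalized to Actb within a sample, and folded
against the **geometric mean** of the CT0 reference group — the
scale-consistent aggregator for ratio data; the reference aggregation is not
dictated by the assay itself. The splicing index divides the exon-specific
by the transcript-level normalized value; the Actb terms cancel
algebraically, so it is computed on normalized values and either input form
works. RT-PCR percent inclusion size-corrects band areas by fragment length
(molar signal = area/bp). The proprietary amplification-curve analysis of
the original instrument is out of scope; the efficiency-corrected transform
stands in for it.

# Motif scanning

The scanner is a log2-odds threshold scan (default 8 bits) on both strands
with a 0th-order background, windows containing N skipped rather than scored
as background. This replaces a probabilistic-segmentation scanner whose
prior is not recoverable; the enrichment contract — per-gene
presence/absence of any clock element, compared between rhythmic and
control splicing-factor sets by a one-tailed Fisher exact test
(hypergeometric upper tail) — consumes only presence calls and is preserved.
The shipped E-box/E'-box/D-box/RRE matrices are consensus-derived synthetic
stand-ins (85% match probability per position, two-fold IUPAC codes split
evenly); curated matrices should be supplied via `read_pssm_file()` for
real analyses. At the default threshold only exact consensus matches score
above threshold for the 6-mers, which makes planted-site recovery exact.

# Reading-frame classification

Skipping an internal cassette exon whose length is not divisible by three
shifts the reading frame; whether the resulting premature termination codon
triggers nonsense-mediated decay is decided structurally: a PTC in the
penultimate exon's territory (downstream of the last exon–exon junction
after skipping) escapes recognition. The classifier applies, in order:
non-coding exon → frame check → CDS-start containment (new N-terminus) →
penultimate position (NMD-insensitive) → last-CDS-exon-before-stop (new
C-terminus) → NMD candidate. The canonical 50-nt junction rule is *not*
applied: the structural reasoning implemented here works at exon
granularity, and adding the finer rule would change classifications the
shipped fixture cannot adjudicate (exon sequences are not included). The
nine-transcript fixture is a synthetic stand-in constructed to carry the
documented per-gene outcomes; its exon lengths are not the real ones, which
live in supplementary material not distributed here.

# Numerical and degenerate-input policy

* Median polish: row sweeps first, `tol = 1e-8` on the largest adjustment,
  `max_iter = 10` (the RMA convention); ties use the mean-of-middle-two
  median. The decomposition reconstructs the input exactly at every
  iteration, so early stopping affects only the effect/residual split, not
  their sum. Note that `stats::medpolish` stops on an L1 plateau and can
  halt at a different point of the same sweep trajectory; oracle tests
  therefore compare at a fixed sweep count.
* Quantile normalization: ties receive the mean of the reference values
  their ranks span; the transform is idempotent to 1e-12.
* Correlation distance of a constant profile is defined as 1 (no shape
  information); hierarchical clustering refuses constant profiles instead.
* Zero-variance contrasts: difference 0 → stat 0, p 1; nonzero difference →
  p 0, flagged degenerate.
* Seeds are mandatory everywhere randomness exists; generators snapshot and
  restore the caller's RNG state.

# Known limitations

* The FIRMA leakage above bounds achievable specificity at small cluster
  sizes; a screen on real arrays inherits it.
* The antiphase exclusion is exact only for the 4-point grid (or grids
  pairing t with t+12); denser designs would warrant harmonic regression,
  which is deliberately out of scope.
* The SNR ranking formula (range over residual SD about a 5-point smooth,
  then two-day Pearson reproducibility) is an implementer's stand-in for a
  shortlisting step whose exact formula is not recoverable; it is exposed
  as a documented, replaceable scoring rule.
* `read_config()` parses a flat `key: value` subset, not full YAML.
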