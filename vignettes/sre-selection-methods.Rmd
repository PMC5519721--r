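---
title: "Selection on splicing-regulatory-element variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on splicing-regulatory-element variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sreselscan)
```

## The scientific problem

Splicing regulatory elements (SREs) are hexameric cis-acting motifs —
exonic splicing enhancers and silencers (ESE/ESS) and intronic splicing
enhancers (ISE) — that recruit RNA-binding factors to activate or repress
nearby splice sites. A single-nucleotide change inside such a hexamer can
destroy the motif (the *disrupting* allele) or create it (the *inducing*
allele), with downstream consequences for exon inclusion. If splicing
regulation has been a substrate of recent selection, SNPs in SREs should show
distinctive patterns of between-population allele-frequency differentiation
and haplotype structure relative to matched non-SRE SNPs of the same
functional class.

This package reimplements the full analytical machinery for that question as
a tested pipeline: hexamer-level SRE annotation with exon-skipping context,
per-SNP and multilocus selection statistics, stratified enrichment tests with
matched null sets, and SRE-partitioned heritability — all exercised against a
synthetic-data generator with known planted truth, since the original cohort
inputs (genome-scale phased panels, QTL catalogues, GWAS summary data) are
not redistributable at desk scale.

## SRE annotation

For a SNP at position $p$ the annotator extracts the 11-base context
(5 bases either side). With each allele substituted at the center, it
enumerates the six hexamer windows obtained by placing the SNP at the last
window position and sliding until the SNP is at the first position, and tests
each window for an exact match in the motif list. A SNP is an SRE SNP iff
(i) at least one allele matches at least one motif, and (ii) the exon-skip
geometry holds for the matched element type: ISE candidates must lie in an
intron immediately flanking a skipped exon; ESE/ESS candidates must lie
inside a skipped exon. An exon is *skipped* iff some isoform of the gene
contains it while another isoform omits it but retains both flanking exons.

Design choices the source method leaves open, fixed here:

* **Strand.** Motif matching is performed on the transcribed strand of the
  host gene (contexts of minus-strand genes are reverse-complemented before
  windowing), because SRE hexamers are defined on pre-mRNA. Reported
  inducing/disrupting alleles are translated back to reference-strand (VCF)
  bases. A `transcribed_strand = FALSE` switch matches on the reference
  strand instead.
* **"Immediately adjacent".** Any position within a directly flanking intron
  qualifies, with no distance cap.
* **Ambiguity.** A SNP whose two alleles both match motifs (same or different
  element types) is retained as an SRE SNP but its allelic direction is
  recorded as `ambiguous` and it is excluded from disrupt/induce contrasts,
  which require an unambiguous direction.
* **Junction distance** is the bp distance to the nearest exon/intron
  boundary of the host gene, 0 for the first base on either side of a
  junction.
* **Functional class**: `intronic` for intron-interior SNPs; coding classes
  by strand-aware codon comparison (`synonymous`, `non-synonymous`; stop gain
  or disruption of the canonical splice dinucleotides gives `LOF`); `other`
  for UTR/intergenic. Frameshift is impossible here because only SNPs are
  modeled.

## Selection statistics

**F_ST.** The Weir–Cockerham (1984) two-population per-locus estimator,
computed from haploid (haplotype) counts with the heterozygosity component
zero under the haploid convention. Per-locus estimates may be negative; they
are kept in output and clipped to zero only for bin assignment. For
*combining* loci the package uses the estimator's own multi-locus form
$\hat\theta = \sum_\ell a_\ell / \sum_\ell (a_\ell + b_\ell)$: the arithmetic
mean of per-locus ratios is substantially biased downward (measured ≈ 0.21 at
a true 0.30 with 50 diploids per population), while the ratio of summed
components recovers the generating divergence to within ±0.01.

**EHH, iHS, XP-EHH.** EHH at distance $d$ from a core allele is the
probability that two random distinct carrier haplotypes are identical over
all sites between the core and $d$. Curves are computed site by site outward
and stopped when EHH < 0.05 or at the chromosome end (boundary-truncated
integrals are the known limitation of short panels); integrals use the
trapezoid rule on genetic distance, summed over both directions. iHS is
$\log(\int \mathrm{EHH}_{\text{ancestral}} / \int \mathrm{EHH}_{\text{derived}})$ —
so extended homozygosity on the *derived* background yields negative raw
values; since outliers are called on $|iHS| \ge 2$ the orientation does not
affect calls. XP-EHH is the same log-ratio between populations for a
designated allele (the derived allele where known, otherwise ALT; positive =
longer haplotypes in population 1). iHS is standardized to mean 0, variance 1
within derived-allele-frequency bins of width 0.05 (bins with fewer than 20
defined scores are merged with a neighbor); XP-EHH is standardized in a
single global bin.

**XP-CLR-style composite likelihood.** At each window of $k = 50$ SNPs
(grid step 10), the null likelihood of the tested population's frequencies is
a truncated normal on $[0,1]$ centered at the reference-population frequency
with variance $\omega\,\bar p(1-\bar p)$, where $\omega$ is a
method-of-moments drift scale estimated genome-wide (mean of
$(p_2-p_1)^2/(\bar p(1-\bar p))$ minus the binomial sampling contribution
$1/n_1 + 1/n_2$, floored at $10^{-6}$). The alternative shifts each SNP's
expected frequency toward fixation by a sweep effect $s$ decayed with genetic
distance from the window center, $e^{-d/\delta}$, maximized over a fixed grid
$s \in \{0, 0.05, \dots, 0.5\}$, $\delta \in \{0.01, 0.1, 1\}$ cM. Two
numerical choices stabilize this simplification of the full hitchhiking
model, and both were adopted after the naive variant demonstrably failed to
separate planted sweeps from drift:

* the variance scale uses the **pooled** frequency $\bar p$ rather than the
  reference frequency, so that sites monomorphic in the reference but
  polymorphic in the test population (which the generator produces routinely)
  do not collapse the modeled variance and dominate the null distribution;
* the shift **direction is free per SNP** while $s$ and $\delta$ are shared
  across the window, because a swept haplotype drags each linked site toward
  whichever allele it happens to carry — a single window-wide direction
  cannot represent the planted (or real) signal.

CLR $= 2(\max_{\text{alt}} \log L - \log L_0) \ge 0$ by construction since
the grid contains the null. Scores are reported per variant as the maximum
over covering windows. This is a deliberately reduced form of the published
XP-CLR; what it preserves — and what the tests certify — is the contract that
sweep windows separate from the simulated null distribution.

**Composite of composites.** Per variant,
$L(x) = f_{F_{ST}}(x)^\alpha f_{XPEHH}(x)^\beta f_{XPCLR}(x)^\gamma$ with the
component densities estimated by 50-bin histograms with add-one smoothing
from the panel-wide empirical distributions, reported as $\log L$. The
exponents default to $\alpha=\beta=\gamma=1$; no estimation procedure for
them is defined, so they are exposed as configuration only.

## Enrichment machinery

Odds ratios follow the probability form
$OR(F;S) = \frac{P(F|S)/(1-P(F|S))}{P(F|S^c)/(1-P(F|S^c))}$, which equals
$ad/bc$ on the 2×2 table; p-values are two-sided Fisher exact (the source
analysis does not say Fisher vs chi-square; Fisher is the conservative
default), with a flagged Haldane–Anscombe 0.5 correction when a cell is
empty. F_ST bins have width 0.1 with extreme flags at $>0.70$ and $<0.05$;
negative estimates fall into the first bin. Conditional odds ratios apply the
same table within feature strata. The Cochran–Mantel–Haenszel common odds
ratio over B-value strata (width 100) is the Mantel–Haenszel estimator
$\sum a_i d_i/n_i \big/ \sum b_i c_i/n_i$ with the continuity-corrected CMH
chi-square; the crude pooled OR is always reported alongside so confounding
inflation is visible. Strata with an empty margin are excluded and counted.

Matched-null empirical p-values draw `n_sets` random sets from a pool with
exactly the target's per-cell composition over the matching bins — B width
100, DAF width 0.05, LD extent $L = \sum r_j^2$ (haplotype $r^2$ with all
neighbors within ±200 kb; the neighbor window is not specified by the source
and is configurable) in the fixed intervals $[0,50)$, $[50,85)$, $[85,110)$,
$[110,140)$, $\ge 140$ — and report $p = (\#\{null \ge obs\}+1)/(n+1)$,
so the analysis convention `n_sets = 1000` reports "< 0.001" at saturation.
Cells with too few pool candidates fall back to sampling with replacement
(flagged); a cell with an empty pool is an error naming the cell. MAF
(width 0.05), gene-size (pool quintiles) and junction-distance (pool
quartiles) bins are optional additions with documented default widths, which
the source leaves unstated. Note the uniformity guarantee for the empirical p
holds for continuous set statistics; counting statistics tie across null sets
and make the p conservative.

Rank comparisons use a Mann–Whitney U with exact two-sided p by the no-ties
counting recursion when both samples have ≤ 12 observations, otherwise the
tie-corrected normal approximation with continuity correction (matching
`wilcox.test`'s conventions, against which it is cross-checked). KS
comparisons (one-sample against Uniform(0,1) or two-sample) also emit a Q-Q
table of expected vs observed $-\log_{10} p$ for external plotting.

## Fitted models

**SRE-overlap logistic model.** $p_i = 1/(1+e^{-(\beta_0 + \beta\cdot\Delta)})$
with features $\Delta$ = (DAF, F_ST, B, L). Fit by hand-rolled IRLS
(convergence $\max|\Delta\beta| < 10^{-8}$, cap 100 iterations), with
features z-scored internally for conditioning and coefficients, standard
errors and Wald tests back-transformed to the original scale; `stats::glm` is
the cross-check oracle in the test suite, never the implementation. The
intercept absorbs genome-wide effects (demography); the coefficients measure
locus-specific effects on SRE membership. Perfect separation is detected and
reported with the offending feature; rank-deficient designs are errors.

**SRE-partitioned heritability.** $y = Xb + g_{SRE} + g_{nonSRE} + e$,
$\mathrm{var}(y) = A_{SRE}\sigma^2_{SRE} + A_{nonSRE}\sigma^2_{nonSRE} +
I\sigma^2_e$, with the standard normalized GRMs
$A = \frac1m \sum_k (g_k - 2p_k)(g_k-2p_k)^\top / (2p_k(1-p_k))$
(monomorphic SNPs excluded and counted; the exact GRM normalization is not
stated by the source, so the standard form is adopted). Estimation is
average-information REML with EM fallback steps whenever an AI update would
decrease the restricted likelihood or exit the parameter space; components
are floored just above zero; convergence on $|\Delta \log L| < 10^{-6}$.
$h^2_{SRE} = \hat\sigma^2_{SRE}/(\hat\sigma^2_{SRE} + \hat\sigma^2_{nonSRE} +
\hat\sigma^2_e)$ with a delta-method SE from the inverse AI matrix. Fixed
effects default to an intercept; binary traits are analyzed on the observed
scale with no liability transformation (the source's scale is unstated;
recorded as a limitation).

## The synthetic world

The generator's defaults are the conditions the pipeline is certified under,
chosen once:

* **Divergence**: Balding–Nichols with $c = 0.15$ (continental-scale
  differentiation); ancestral frequencies Uniform(0.05, 0.95); population
  frequencies Beta$(p_0(1-c)/c,\,(1-p_0)(1-c)/c)$, so $c$ *is* the expected
  F_ST — a closed-form recovery target.
* **Panels**: 50 diploids (100 haplotypes) per population. Per-site counts
  are exact Binomial draws; local LD comes from building haplotypes as
  mosaics of a 25-founder pool with per-site template-switch probability
  0.05, then applying frequency-correcting flips. This produces extended
  haplotype sharing on a ~10-site scale and adjacent-site $r^2$ several-fold
  above the long-range background, but it is *not* a coalescent: LD decay,
  allele-frequency spectra and recombination-map structure of real data are
  not reproduced. A green test certifies the statistics' contracts, not
  demographic realism.
* **Sweeps**: a fraction $f$ (default 0.8 in the acceptance fixture) of the
  carriers of a favored core allele are replaced by copies of one template
  haplotype over ±100 sites — the cheapest construction that produces the
  EHH/XP-CLR contrast the statistics detect. The core is planted at an
  intermediate-frequency site (0.4–0.6), where these statistics are designed
  to operate; low-frequency cores give few carriers and weak signals.
* **Genes and motifs**: 20 genes (random strand) of five 90-bp exons and
  300-bp introns; about half get a skipping isoform. SRE plants write a
  motif hexamer into the transcribed-strand context so that exactly one
  allele matches (verified by brute-force rejection sampling at construction,
  up to 1000 attempts); non-SRE plants verify that neither allele matches any
  motif. Functional-class truth is set by codon arithmetic on the emitted
  sequence. The demonstration motif sets are 50 random disjoint hexamers per
  element type — real analyses must supply published hexamer lists.
* **Ancestral alleles**: reference 80%, alternate 15%, unknown 5% (variants
  with unknown ancestral state are retained for F_ST/enrichment and excluded,
  with a reason code, from DAF-dependent statistics).
* **B values**: piecewise-constant 5-kb segments drawn uniformly from
  {100, …, 1000}, independent of genotypes by default; a separate confounded
  generator (`simulate_confounded_strata`) correlates B with both SRE status
  and high F_ST at a fixed within-stratum OR to exercise the CMH adjustment.
* **Genetic map**: uniform 1 cM/Mb unless a map table is supplied.

## Numerical conventions and degenerate inputs

Internal coordinates are 0-based half-open with conversion only at format
boundaries; interval tracks use BED semantics (a 1-based query q tests
containment of q−1). Only biallelic phased SNPs enter the pipeline; indels,
multi-allelic and unphased records are dropped and counted. Undefined
statistics are NA with a reason code, never silent zeros: monomorphic loci
(F_ST), < 2 carriers or zero integrals (iHS/XP-EHH), unknown ancestral state
(DAF, iHS), monomorphic focal variants (LD extent), empty margins (CMH
strata), all-constant standardization bins. Monomorphic frequencies entering
the XP-CLR density are nudged to $1/(2n)$.

## Scaling choices in the test suite

The certified properties are sample-size invariant, so the suite runs them at
reduced scale to fit a single-CPU budget: GREML recovery at n = 800
individuals and 2,000 SNPs over 50 seeds (rather than n = 2,000 and 5,000
SNPs); sweep detection on 160-haplotype × 1,000-SNP panels over 20 seeds;
empirical-p calibration with 200 replicates of 200 null sets over a 3,000-SNP
pool. Thresholds (±0.01 on F_ST recovery, standardized XP-EHH > 2, top-1%
null rank, 5% on the CMH common OR, 2·SE coverage in ≥ 90% of seeds) are
unchanged.

## Known limitations

* The XP-CLR component is a reduced sweep model (distance-decayed frequency
  shift), not the full hitchhiking transition density; its scores are
  comparable within a run against its own simulated null, not against
  published XP-CLR values.
* EHH-based statistics on short synthetic contigs are boundary-truncated;
  integrals are comparable within a panel, not across panels of different
  extent.
* Heritability of binary traits is estimated on the observed scale.
* The annotation assumes exon-skipping as the only alternative-splicing event
  class, single-base substitutions only, and exact hexamer matching (motif
  lists are inputs; no neighborhood scoring).
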