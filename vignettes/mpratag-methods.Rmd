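---
title: "mpratag: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mpratag: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpratag)
```

# The experiment this package analyzes

A pool of reporter plasmids is transfected into cultured cells. Each plasmid
carries one short regulatory element — here, the ancestral or the derived
allele of a transcription factor binding site (TFBS) with 25 nt of genomic
flank on each side — upstream of a minimal promoter, and a random 20-nt tag
in the transcribed region that uniquely identifies the construct. After
transfection, three libraries are sequenced per replicate:

* **RT+** — tags amplified from reverse-transcribed RNA: the signal.
* **RT−** — tags amplified from the same RNA preparation *without* reverse
  transcription: a direct measurement of plasmid-DNA carryover.
* **DNA** — tags amplified from plasmids recovered from the cells: the molar
  ratios of the constructs that were actually delivered.

Because both alleles are measured in the same pool, in the same cells, with
the same promoter, the allelic comparison is internally controlled: cell
number, transfection efficiency, and sequencing depth cancel in the ratio.

# The per-replicate statistic

For a variant with derived-allele counts $d$ and ancestral-allele counts $a$
in one replicate, the activity statistic is

$$
\mathrm{da} \;=\;
\ln\!\left(
\frac{(d_{RT+} - d_{RT-}) \,/\, (a_{RT+} - a_{RT-})}
     {d_{DNA} \,/\, a_{DNA}}
\right).
$$

The RT− subtraction removes DNA carryover from the RNA signal; the division
by the DNA ratio corrects for unequal molar ratios of the two plasmids in the
transfected cells ("normalization" is division — adding the correction would
not remove the molar-ratio dependence). The same formula with the negative
control in the denominator role measures each allele's activity relative to
the bare minimal promoter.

Two degeneracies arise with count data and are handled explicitly rather than
floored:

* a background-subtracted RNA count ≤ 0 (`nonpositive_after_subtraction`),
* a zero DNA count (`zero_denominator`).

Such replicates are *dropped* from that variant's test with a recorded
reason. Flooring (e.g. adding a pseudocount) would pull the mean toward an
arbitrary value; with 10 replicates, dropping one or two is the smaller
distortion, and the per-replicate table records exactly what was dropped and
why.

The statistic is invariant to common scaling of the four RT counts and to
common scaling of the two DNA counts (sequencing depth cancels), and
antisymmetric under swapping the two constructs. Both properties are exact in
real arithmetic; the test suite asserts them to 1e-12 in floating point (and
bit-exactly for power-of-two depth scalings, where IEEE arithmetic preserves
quotients).

# Replicate quality control

Occasionally a replicate's RT− library blows up (incomplete DNase digestion)
or its RT+ library collapses (failed transfection or RT). The automated rule:
replicate $r$ is excluded for a construct when its normalized RT− count
exceeds $\mathrm{median} + k\cdot\mathrm{MAD}$ of the other replicates, or
its normalized RT+ count falls below $\mathrm{median} - k\cdot\mathrm{MAD}$
of the others — one-sided in each direction, leave-one-out, with $k = 3$ and
the scaled MAD (consistency constant 1.4826, i.e. 3 robust standard
deviations). With fewer than 4 replicates the rule is disabled (a MAD of 3
values is meaningless) and only external exclusions apply.

**Choice of normalizer.** The pipeline divides RT+ and RT− counts by the
*DNA-channel* total of the same replicate, not by each channel's own total.
The failure modes above scale a whole channel; after within-channel
normalization a uniformly inflated RT− library has exactly the same
proportions as a healthy one and is undetectable. The DNA library is
unaffected by RT/carryover pathologies, so it is the stable per-replicate
depth reference that keeps whole-channel failures visible.
`qc_flag_replicates()` takes the normalizing totals as arguments, so pure
within-sample normalization remains available to callers who want it.

A manually curated exclusion list (the practice the automated rule emulates)
is accepted as an unconditional override, scoped either to a whole replicate
or to one construct in one replicate.

# Testing and multiplicity

Per variant and cell line, the valid replicate values are tested with a
two-sided one-sample t-test of mean 0 ($t = \bar{x}/(s/\sqrt{n})$,
$df = n-1$). This assumes the per-replicate log ratios are approximately
normal and independent — reasonable for logs of moderately deep counts across
independent transfections, and the synthetic null (below) confirms the
nominal type-I rate under the generative model. Degenerate cases follow a
fixed contract: $n < 2$ → untestable (reported, not fatal); $s = 0$ with
mean ≠ 0 → $p = 0$ with a degeneracy flag; $s = 0$ with mean 0 → $p = 1$.

P-values are Benjamini–Hochberg adjusted **within each cell line**. The
derived-vs-ancestral tests (one per variant) and the vs-negative-control
tests (two per variant) are heterogeneous hypothesis families, so by default
they are corrected as two separate families per cell line;
`bh_family = "combined"` merges them. Significance is $q < 0.05$
(configurable `alpha`).

Mean log ratios are reported on a signed fold-change scale:
$e^{m}$ for $m \ge 0$, $-e^{-m}$ otherwise, so the scale has no values
between +1 and −1 and both ±1 mean "no difference". Cross-cell-line
agreement is summarized by pairwise Pearson correlation of the per-variant
mean log ratios (pairs with fewer than 3 shared testable variants, or zero
variance, are flagged rather than reported).

# The synthetic generator

`simulate_library()` / `simulate_counts()` / `simulate_reads()` emulate the
full experiment with known truth. Defaults state the emulated design: 25 SNV
allele pairs, 3 cell lines, 10 transfection replicates, one tag per
construct, depth 1e5 per sample.

Per replicate and cell line:

1. plasmid copy numbers $c_i \sim \mathrm{Lognormal}(0, \sigma)$ around
   equimolar ($\sigma = 0.4$ by default — pooled overnight cultures are equal
   by volume, not by molarity; within-few-fold imbalance is what the DNA
   normalization exists to absorb);
2. DNA counts $\sim \mathrm{Multinomial}(\text{depth}_{DNA}, \propto c_i)$;
3. RNA rates $\alpha_i c_i g_i$ with a per-construct gamma multiplier
   $g_i \sim \Gamma(k, k)$ (mean 1, default shape $k = 20$, i.e. ~22% CV):
   transfection and PCR jackpotting make replicate noise far exceed counting
   noise, and a single shape parameter controls it;
4. RT+ counts $\sim \mathrm{Poisson}(s\,(\alpha_i + \kappa)\,c_i\,g_i)$ and
   RT− counts $\sim \mathrm{Poisson}(s\,\kappa\,c_i)$ on a **common** scale
   $s$ fixed by the RT+ depth, with carryover $\kappa = 0.05$ by default.

Step 4 deliberately uses coupled Poisson channels instead of two independent
fixed-depth multinomials: the analysis subtracts *raw* RT− counts from raw
RT+ counts, which is meaningful only if the two libraries sit on the same
per-molecule scale — as they do in the emulated protocol, where both derive
from the same RNA aliquot with matched amplification. Independent fixed-depth
channels would make the subtraction biased (breaking the generator's
guarantee that the estimator's expectation is $\ln \rho$) and would make
whole-channel outliers invisible. Setting `depth_rtminus` away from
`depth_rtplus` deliberately re-introduces that bias for robustness studies.

Activities: the negative control defines baseline 1; ancestral alleles are
`enhancer_strength` × baseline (default 2 — candidate enhancers mostly above
baseline); derived alleles multiply that by the true ratio $\rho_v$
(`activity_ratios`, default 1 = null); the positive control is 20× baseline
and is never analyzed statistically. Outlier injection multiplies a targeted
replicate's RT− (or RT+) channel rates by a factor, emulating the
replicate-level failures the QC rule exists to catch.

Reads are assembled as cloning site + insert + cloning site + spacer +
tag cassette (5′ anchor `TCTAGATAG`, 20-nt tag, 3′ anchor `GGCCGGCC`), one
read per counted tag occurrence, with an optional uniform substitution error
rate. Simulated flanks and tags are screened against the four restriction
sites involved (KpnI, NheI, XbaI, FseI) — as real cloned inserts must be,
since the enzymes would cut them — which guarantees every read carries
exactly one well-formed tag cassette and makes the error-free round trip
(reads → association → counting) exact. The insert-less negative control is
recognized in association reads by its adjacent KpnI/NheI junction
(`GGTACCGCTAGC`); this is vector-layout configuration, not a constant of the
analysis.

**What a green synthetic test does not establish.** The generator draws
independent lognormal copies per replicate (no shared pool-composition
effects), uses a single overdispersion scale for all constructs, makes no
cell-line-specific trans-acting model (true $\rho_v$ is shared across cell
lines), and simulates substitution errors only (no indels, no quality
scores). Calibration and recovery under this model support the arithmetic
and the inferential machinery, not the biological fidelity of any real
dataset.

# Tag processing choices

* **Exact tag matching, no error correction.** Random 20-mers in a ~52
  construct pool are far apart in expectation; a 1-mismatch neighbour of a
  whitelist tag is discarded, not rescued. Mismatch-tolerant matching is out
  of scope.
* **`min_support = 2`** reads for a unique tag→construct assignment, to
  suppress chimeric/PCR singletons.
* Reads whose 5′ anchor occurs more than once are discarded as chimeric;
  tags seen with two or more constructs are `ambiguous` and never counted.
* Count conservation holds by construction: counted + discarded = input
  reads.

# Acceptance-scale choices

* The type-I criterion pools 40 independent *default-sized* null experiments
  (25 variants each) to reach 1,000 simulated variants, keeping the stated
  per-construct depth, and checks the raw $p < 0.05$ rate against the 99%
  binomial band around 0.05.
* "Within Monte-Carlo error" for effect recovery at $\rho = 1.8$ is
  operationalized a priori as $|\bar{m} - \ln 1.8| \le 3\,\mathrm{SE}$ with
  $\mathrm{SE} = \mathrm{sd}(\text{per-variant means})/\sqrt{n}$.
* Outlier-QC sensitivity counts an injected replicate as flagged when the
  high-RT− reason is set for the majority of variant constructs in that
  replicate.

# Known limitations

* The t-test takes per-replicate log ratios as exchangeable; no variance
  shrinkage across variants (limma/DESeq2-style) and no count-model
  alternative is offered — matching the emulated analysis, not improving it.
* Indel alleles are supported in the library and arithmetic, but the
  simulator generates SNV pairs only.
* Reproducing a published dataset requires its per-tag count tables and any
  manual exclusion flags as external inputs; the package ships none.
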