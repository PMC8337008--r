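---
title: "Estimating splice site usage with a segment-inclusion Markov chain"
author: "SpliceChain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating splice site usage with a segment-inclusion Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceChain)
```

## The problem

Alternative splicing lets one gene express several mRNA isoforms.
Short-read RNA-seq makes full-length isoform reconstruction ill-posed,
while event-based metrics (PSI and relatives) only quantify predefined
local patterns. SpliceChain takes a third route: it models the splicing
*process* through the usage of individual splice sites, a small set of
interpretable parameters that can generate arbitrarily complex splicing
patterns, and estimates all of them jointly from all reads mapped to a
gene.

## The model

A gene's distinct exon start sites (3' acceptors, plus alternative
transcription start sites) and exon end sites (5' donors, plus
alternative transcription end sites) cut it into $M$ segments
$X_1,\dots,X_M$ in transcription direction. Any transcript is a binary
inclusion vector $Z = (Z_1,\dots,Z_M)$, $Z_i = 1$ if segment $i$ is
transcribed. The gene's outermost TSS and TES bound the first and last
segment and carry no parameter, so $M = M_s + M_e + 1$ where $M_s$ and
$M_e$ count modeled start and end sites.

$Z$ follows an inhomogeneous two-state Markov chain:

* $P(Z_1 = 1) = \pi$, the proportion of transcripts containing the
  first segment;
* at a start site $s_m$: $P(Z_{i+1}=1 \mid Z_i=0) = p_m$ and
  $P(Z_{i+1}=1 \mid Z_i=1) = 1$ — an ongoing exon ignores acceptors;
* at an end site $e_m$: $P(Z_{i+1}=0 \mid Z_i=1) = q_m$ and
  $P(Z_{i+1}=0 \mid Z_i=0) = 1$ — an intron ignores donors.

$p_m$ and $q_m$ are the *conditional usages*: the probability a site is
used given the process considers it. The terminal TES is used with
conditional probability 1 by construction. The all-zero path has
positive probability $(1-\pi)\prod_m(1-p_m)$; it is retained (the chain
is left exactly as defined) but cannot emit reads, because its
effective length is zero, so it never distorts the read model.

Reads of fixed length $L$ are generated by drawing a transcript with
probability proportional to $l(Z)\,w_\Theta(Z)$ — effective length
$l(Z) = \max(tl(Z) - L + 1,\, 0)$ times chain probability — and then a
start position uniformly among the $l(Z)$ possibilities. The *mapping
signature* of a read is the ordered set of segments it overlaps; reads
with equal signatures are exchangeable, so the signature counts
$c_1,\dots,c_J$ (summing to the read total $N$) are the sufficient
statistics. The probability of a signature $g$ factorizes as

$$P(g \mid \Theta) \;=\; \frac{\mathrm{spc}(g)\; P(Z \sim g \mid
\Theta)}{\sum_{Z'} l(Z')\, w_\Theta(Z')},$$

where $\mathrm{spc}(g)$ counts the start positions that generate $g$
(a purely geometric quantity: the read starts in $g$'s first segment,
ends inside its last, and covers the intermediate retained segments
completely), and $Z \sim g$ fixes $Z$ to 1 on $g$'s segments and 0 on
the segments $g$ splices over, marginalizing the rest. The probability
is independent of the marginalized segments because a read that reached
them would carry a different signature.

## Inference

`emFit()` maximizes the observed-data likelihood
$\sum_j c_j \log P(g_j \mid \Theta)$ by EM:

* **E-step.** For each signature, a forward–backward pass over the
  chain conditioned on the signature's span pattern yields expected
  counts of every boundary transition and of the initial state. The
  posterior over paths given a read depends only on consistency with
  the span pattern, because $\mathrm{spc}(g)$ does not depend on the
  marginalized segments.
* **M-step.** The expected complete-data log-likelihood is a sum of
  Bernoulli terms minus $N \log D(\Theta)$, with $D$ the expected
  effective length. $D$ is *linear* in each individual parameter, so
  each conditional maximization is the root of a quadratic and is
  solved in closed form; parameters are updated cyclically (an ECM
  scheme). Every conditional update increases the expected objective,
  so the observed log-likelihood never decreases.

$D(\Theta)$ is computed exactly by dynamic programming over segments
and transcribed-length buckets capped at $L$ (cost $O(ML)$), with the
overflow mass beyond the cap carried as an aggregated excess — no
approximation is involved for genes of any length.

Numerical choices: parameters are clamped to $[10^{-9}, 1-10^{-9}]$
during iteration (estimates at the boundary are flagged); probabilities
of forced transitions that are exactly zero short-circuit to $-\infty$
in log space; convergence is declared when the relative log-likelihood
change falls below `tol` (default $10^{-6}$, at most 1000 iterations);
the default initialization is the maximum-entropy value 0.5 for every
parameter, with seeded random restarts if the likelihood is not finite
at the start. Because EM converges only linearly along low-curvature
directions, the converged solution is optionally refined by a
box-constrained quasi-Newton ascent of the observed log-likelihood
(`polish = TRUE`, kept only when it improves the fit); on small genes
the refined optimum matches direct numerical maximization of a
brute-force enumeration likelihood to $10^{-6}$ in log-likelihood and
$10^{-4}$ in the identifiable parameters.

### Identifiability

A parameter with no read support cannot be estimated:
`checkIdentifiability()` flags a boundary parameter when no signature
overlaps either adjacent segment, and $\pi$ when the gene has a single
segment (the likelihood is then constant in $\pi$) or no signature
covers segment 1. Flagged parameters are reported as `NA` in output
tables. The flag is deliberately structural and conservative: a
parameter can be flagged estimable yet weakly determined when, e.g., a
segment is shorter than the read length, or when transcripts that
decline a start site are short and therefore down-weighted by the
effective-length factor. The bootstrap intervals, not the flag, are the
package's statement about precision.

### Conditional versus marginal usage

The conditional usages are the model parameters; the *marginal* usage
of a site — the fraction of transcript output in which an exon actually
starts or ends there, $P(Z_i{=}0)\,p_m$ or $P(Z_i{=}1)\,q_m$ — is what
a ground-truth comparison against known transcript abundances measures.
`marginalSiteUsage()` reports both; output tables carry the conditional
estimate in `estimate` and the marginal alongside, and the two coincide
exactly at sites every transcript "considers". Downstream comparisons
should pick the column matching their definition of usage.

## Uncertainty

`bootstrapFit()` draws $B$ replicates
$c^b \sim \mathrm{multinomial}(c_1/N,\dots,c_J/N;\, N)$, refits each,
and reports percentile intervals (inverted-ECDF quantiles, so $B = 2$
degenerates to the min/max of the two replicates) at the requested
level, per identifiable parameter. Runs are deterministic given a seed.
The default $B = 100$ balances stability against runtime; coverage of
the generating parameters in simulations at $B = 200$ over 100
repetitions lies in the nominal range. `ciOverlap()` exposes the
two-individual comparison used when contrasting a variant carrier with
a control; no multiple-testing correction is applied, which inflates
false positives when many sites are screened — a known limitation of
the interval-overlap procedure.

## The simulator and what it does (not) emulate

`simulateReads()` implements the generative model exactly: transcripts
drawn with probability $\propto l(Z) w_\Theta(Z)$ by full path
enumeration (hence a guard $M \le 20$), uniform read starts, signatures
derived from the covered segments. It returns the exact ground truth —
transcript abundances and per-boundary true usages via
`trueUsageFromAbundances()` — and can emit a toy SAM file so the
BAM-based counting path is exercised end to end.

The simulator deliberately omits sequencing errors, fragment-length
and positional bias, multi-mapping ambiguity and novel splice sites.
Passing tests therefore demonstrate correctness of segmentation,
counting, likelihood, optimization and resampling under the model's own
assumptions — not robustness to the additional noise of real libraries.
Paired-end data are handled by treating each mate as an independent
single-end read; soft-clipped bases are ignored; only primary
alignments are counted; with variable read lengths the modal length is
used and other reads are skipped with a tally.

Evaluation uses the per-site Bernoulli Kullback–Leibler divergence
$u\log(u/\hat u) + (1-u)\log\{(1-u)/(1-\hat u)\}$ (natural log,
$0\log 0 = 0$, $\hat u$ clamped to $[10^{-6}, 1-10^{-6}]$), computed by
`klScore()`; summaries exclude sites whose true usage is exactly 0 or 1
so that only alternatively used sites are scored.

## Worked example

```{r example}
seg <- buildSegmentation(exampleTranscripts())
seg

theta <- ChainParameters(0.55, p = c(0.30, 0.65, 0.40, 0.70),
                         q = c(0.45, 0.60, 0.35))
sim <- simulateReads(seg, theta, N = 20000, L = 100, seed = 7)
fit <- emFit(sim$counts, seg)
fit
head(usageTable(fit, seg, sim$counts))
```

## Design choices and problem sizes

* **Coordinates.** GTF input is 1-based inclusive; internally all
  arithmetic uses 0-based half-open gene coordinates oriented in
  transcription direction (minus-strand genes are flipped), and output
  coordinates are converted back to 1-based genomic positions.
* **Gene units.** Transcripts sharing a `gene_id` but occupying
  disjoint loci are split by `splitGeneLoci()` into one chain per
  contiguous locus, since the model assumes one TSS-to-TES span.
  Overlapping or antisense genes are treated as separate units defined
  by `gene_id`.
* **Alternative TSS/TES.** Inner transcription starts and ends are
  modeled as ordinary start/end sites with parameters; only the
  outermost pair is unmodeled.
* **Worked example realization.** The bundled three-transcript gene
  uses segment lengths of at least 1.5 times a 100 bp read so that
  every segment can contain reads entirely; segments shorter than the
  read length are legal but leave the adjacent usages only weakly
  determined (reads cannot resolve them individually), which inflates
  estimator spread without biasing it.
* **Test problem sizes.** The suite checks DP quantities against full
  enumeration on genes with up to 12 segments and reads of 12-20 bp;
  parameter recovery uses $10^3$ and $10^5$ simulated 100 bp reads on
  the example gene; bootstrap coverage uses 100 repetitions of $B=200$
  replicates at $N=2000$ reads. At the example gene's depth of
  $10^5$ reads the per-parameter sampling SD of the maximum-likelihood
  estimator, from the Fisher information of the signature distribution,
  ranges from 0.003 to 0.018 — largest for start sites whose
  "declined" paths are short transcripts down-weighted by the
  effective-length factor. Recovery assertions are calibrated to that
  spread.

## Limitations

The chain is first-order: long-range coordination between splice sites
(e.g. between intron removal events) is not represented, so implied
full-length transcript frequencies are less trustworthy than the
site-level usages themselves. Novel splice sites are not discovered
from reads — the segmentation is annotation-driven, and junction reads
incompatible with it are discarded (tallied). TSS/TES usage estimates
from short-read data are intrinsically unreliable and should be read
with caution even though the model formally provides them. No
fragment-length model, bias correction or multi-mapper rescue is
attempted.
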