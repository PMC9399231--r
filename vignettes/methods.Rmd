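---
title: "Methods: statistical models and design of the enhancerflow pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical models and design of the enhancerflow pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`enhancerflow` analyses how laminar shear stress (LSS) remodels the
endothelial enhancer landscape relative to static culture (ST). This
vignette is the package's own account of its science: the model behind
each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the design was genuinely open.

## Coordinate conventions and interval algebra

All internal coordinates are 0-based half-open (BED convention); GTF
input (1-based inclusive) is converted at the I/O layer. A single
convention everywhere prevents off-by-one drift between stages. Merging
treats book-ended intervals (end equal to the next start) as
overlapping, matching the bedtools-merge default of distance zero.
Nearest-gene distances are measured from the peak centre to the TSS
(the cited annotation tool's convention; the choice of anchor point is
not otherwise forced), with exact ties broken by the lexicographically
smallest gene identifier so results are deterministic.

## The negative-binomial Wald engine

One engine tests differential accessibility (DAR), expression (DEG),
transcription-factor binding (DBR) and loop strength. It is a
deliberately transparent, simplified DESeq2-style test — the statistic
is implemented, not delegated — and its validity is established by
calibration and power on simulated truth rather than numerical
equality with any external tool.

* **Normalisation.** Median-of-ratios size factors: for sample $j$,
  $s_j = \mathrm{median}_i\, k_{ij}/g_i$ over features $i$ whose counts
  are positive in every sample, where $g_i$ is the feature's geometric
  mean across samples; factors are rescaled to geometric mean 1. When
  no qualifying feature exists (very sparse matrices, e.g. loop
  counts), per-sample totals are used instead; loop matrices override
  the factors with total retained pair counts, which is the
  appropriate exposure for contact data.
* **Dispersion.** With 3 replicates per condition a per-feature
  method-of-moments estimate
  $\hat\alpha_i = (s^2_i - \bar\mu_i \overline{1/s})/\bar\mu_i^2$
  (pooled within-condition variance $s^2_i$) is far too noisy on its
  own. It is therefore shrunk 50/50 toward a mean-dispersion trend
  $\alpha(\mu) = a_0/\mu + a_1$ fitted across features by least
  squares, floored at $10^{-8}$. The fixed 50/50 weight stabilises
  3-vs-3 designs without implementing empirical-Bayes machinery; the
  package's null harness (`generate_null_counts`) verifies that the
  resulting raw p-values are calibrated near the nominal level.
* **Wald statistic.** $\log_2\mathrm{FC} =
  \log_2((\hat\mu_A + 0.5)/(\hat\mu_B + 0.5))$ with a pseudocount of
  0.5 on the normalised group means so the fold change is defined at
  zero counts; the standard error comes from the delta method with
  $\mathrm{Var}(K/s) = \mu/s + \alpha\mu^2$, and the p-value is the
  two-sided normal tail of $\log_2\mathrm{FC}/\mathrm{SE}$. All-zero
  features are reported as $\log_2\mathrm{FC} = 0$, $p = 1$.
* **Significance.** Benjamini–Hochberg adjustment with significance at
  adjusted $p < 0.1$, the cutoff used for every differential readout
  in this analysis. The threshold is interpreted on the adjusted scale
  (the cited tool's default reporting); it is configurable
  (`alpha_sig`).

Because of the pseudocount, rescaling one sample's counts is absorbed
by its size factor exactly only for noiseless (outer-product) data;
on noisy data the invariance holds to within the pseudocount's
$O(0.5/\mu)$ effect. This is the accepted cost of a defined fold
change at zero.

## Motif scanning and enrichment

The scanner scores windows as
$\sum_i \log_2((p_{b_i,i} + 10^{-3})/0.25)$ against a uniform
background, on both strands, calling a hit at 80% of the maximal
achievable score; windows containing `N` never hit. The original
analysis delegated scanning to HOMER, whose exact thresholds and motif
library are version-dependent and not reproducible bit-for-bit; a
transparent scoring scheme with truth-based acceptance replaces them.
Enrichment is an exact upper-tail binomial test: with background hit
rate $p_0$ (clamped to $[10^{-12}, 1-10^{-12}]$), the p-value is
$P(X \ge k_\mathrm{fg} \mid n_\mathrm{fg}, p_0)$. The background set is
the accessible-but-not-differential regions, mirroring enrichment
against the full accessible-region universe. GC-matched background
sampling is not implemented because the synthetic sequences have
uniform composition; with real sequences this is a known limitation.

## Peak annotation and integration

Categories are assigned by the peak centre with fixed precedence
promoter > TTS > exon > intron > intergenic, so every peak gets
exactly one category. The promoter window is TSS ± 3 kb — the
promoter definition used throughout the analysis — and the TTS window
is the transcription end ± 1 kb; both are configurable. The DAR–DEG
correlation pairs every significant DAR with its nearest gene, keeps
pairs whose gene is a significant DEG (all pairs are kept when one
gene is nearest to several DARs; the alternative, deduplicating per
gene, is not applied), and reports Pearson's r with the two-tailed
t-transform p-value. Co-occupancy operationalises "enriched for KLF4
and/or BRG1" as membership in the corresponding differential-binding
result at the same adjusted-p cutoff, with a 1 bp minimum overlap
(bedtools default; no overlap fraction is stated for this analysis).

## Activity-by-Contact scores

Candidate elements follow the printed order of operations: resize each
peak to 250 bp centred on the summit, keep the top-N peaks by read
count (N defaults to 150,000, far above the synthetic peak count, so
the step is exercised by tests rather than by the default run), drop
blacklist overlaps, merge. Activity is the geometric mean of
RPM-normalised ATAC and H3K27ac counts over candidate regions — the
cited ABC method's convention; the source analysis states only that
reads were counted. Contact is $(d + d_0)^{-\gamma}$ with
$\gamma = 1$, $d_0 = 5$ kb (the offset avoids the singularity at
$d = 0$), or, when contact records are supplied, the observed count at
the (element bin, TSS bin) pair normalised so total observed mass
matches total power-law mass at the observed distances, floored at the
power-law value so unobserved bins never drop below the structural
expectation. Each gene's promoter element (TSS ± 250 bp, flagged from
an overlapping candidate or constructed if absent) is always in the
denominator and receives the maximum contact in the window. Scores are
normalised per gene over a 5 Mb window, so they sum to one (or are all
zero in the degenerate all-zero-activity case), and pass at the 0.02
threshold. The pipeline scores genes that are significant DEGs,
following the convention that ABC predictions are made for expressed
genes and this analysis's DEG-centric readout.

## HiChIP loop calling

Paired tags are binned at 1 kb with a minimum interaction size of
1 kb; inter-chromosomal pairs are discarded. The background is a
simplified stand-in for FitHiChIP's spline-plus-regression model:
expected count = (monotone distance decay) × (anchor coverage bias
product), where the decay is the raw mean count per log-spaced
distance bin over all observed *and possible* pairs, made
non-increasing by weighted pool-adjacent-violators, and the bias is
bin coverage over mean coverage. Two numerical choices matter:

* **Leave-self-out bias.** A strong loop inflates both of its anchors'
  coverage; if that inflated coverage enters its own expected count,
  the loop partially absorbs itself into the background. Each pair's
  own count is therefore subtracted from both anchors' coverage before
  computing its bias (floored at half a count).
* **The BH universe.** Upper-tail Poisson p-values are heavily
  discrete; adjusting only the observed pairs would be strongly
  anti-conservative because every singleton at a rare pair has
  $p \approx \lambda < 0.05$ by construction. The step-up therefore
  runs over all testable pairs within the 2 Mb span (an unobserved
  pair has $p = 1$ and enters only through the correction's $m$).
  The foreground is all intra-chromosomal pairs within 2 Mb; the
  calling threshold is $q < 0.01$, the cited tool's default.

Anchors are single 1 kb bins; merging adjacent significant pairs into
anchor clusters is deliberately not performed. Classification marks an
anchor P when it overlaps any TSS ± 3 kb window, E when it instead
overlaps an H3K27ac peak (in the pipeline: candidate regions whose
mean H3K27ac count exceeds `k27_peak_min_mean`); EP loops carry the
gene(s) whose promoter window the P anchor hits. Differential loops
re-use the NB engine on per-replicate loop counts over the union of
loops called in either condition, normalised by total retained pairs;
"gained"/"lost" are significant calls with positive/negative LSS fold
change. Loops selected in one condition and tested for difference
inherit a winner's-curse bias familiar from this two-step design; the
planted-truth tests measure its practical effect.

## The synthetic dataset

`generate_dataset()` is a pure function of its configuration: the same
seed yields byte-identical files. Defaults define the study conditions
the package is tested under: a 10 Mb single-chromosome genome, 120
genes, 800 candidate accessible regions, 150 planted enhancers,
negative-binomial counts with dispersion 0.1 around a baseline mean of
200, planted $|\log_2\mathrm{FC}| = 2$ (half of loci up under LSS,
half down), 3 replicates per condition, contact decay
$(d + 5\,\mathrm{kb})^{-1}$, an 8-fold loop boost, and 200,000 HiChIP
pairs per condition. These sizes keep a full simulate-plus-analyse
round to roughly half a minute on one CPU while leaving every stage
with enough events to measure calibration and recovery.

Choices the generator makes where the study conditions leave the
design open, and why:

* **Planted architecture.** The 150 enhancers are organised into 30
  flow-responsive loci: a target gene regulated by about five
  enhancers placed 10–100 kb from its TSS (log-uniform; real
  enhancer–gene distances concentrate in this range, and the majority
  of DARs lie within 100 kb of a TSS). Target loci are spaced at least
  ~200 kb apart so every planted link is unambiguous — a requirement
  for the truth tables to be well-defined, and a realistic picture of
  multi-enhancer shear-responsive loci. Enhancers of one locus share
  the locus's direction of change, and each link carries a weight in
  $U(0.14, 0.22)$ so target genes change 2.6–4.6-fold — robustly
  detectable at 3-vs-3, as flow-responsive marker genes are; weaker
  targets would make link-recovery evaluations measure DEG power
  rather than the prediction method.
* **Signal levels.** H3K27ac baselines are 15× the ATAC baseline at
  promoter-proximal regions, 4× at planted enhancers and 0.1×
  elsewhere (promoters of expressed genes carry the strongest
  acetylation; accessible-but-inactive background regions carry
  little). KLF4 binds motif regions only; BRG1 follows enhancers and
  promoters; both are multiplied by the planted accessibility effect
  at enhancers. Every gene gets one promoter-proximal accessible
  region, so promoter elements have defined activity.
* **Motifs.** Every planted enhancer carries the consensus of a
  synthetic GC-rich KLF-like 10-mer (shipped as a plain-text fixture;
  no external motif database), inserted at the summit; background
  regions carry it at a 10% decoy rate so enrichment has a non-trivial
  null. Sequences are otherwise uniform A/C/G/T.
* **Contacts.** HiChIP tags are drawn from
  $\lambda(b_1,b_2) \propto w_{b_1} w_{b_2} (d + d_0)^{-\gamma}$ with
  coverage weights $w$ concentrated at region bins in proportion to
  baseline H3K27ac (the assay is H3K27ac-directed); coverage is
  condition-independent so differential loop signal comes only from
  the planted 8-fold LSS boost. The separate Hi-C contact table
  carries a structural 8-fold enrichment at planted enhancer–promoter
  pairs in *both* conditions: loops exist structurally while the
  condition-specific HiChIP readout changes — this is what lets ABC
  (which uses condition-agnostic contact data) recover links whose
  enhancer is active only in the unstressed state.
* **SNPs.** 22 variants are placed inside distinct planted enhancers
  and 8 decoys away from all elements, mirroring the scale of the
  variant intersection in this kind of analysis.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic sequence composition and
GC-bias, overlapping/nested genes and isoforms, chromatin-domain
structure (TADs) and its effect on contact decay, replicate-specific
batch effects, multi-chromosome genomes, and read-level artefacts
(duplicates, mapping errors). Results on real data additionally depend
on upstream peak calling and alignment, which are out of scope here
(the pipeline starts from called peaks and count matrices).

## Numerical conventions and degenerate inputs

Score sums are checked to $10^{-9}$; PWM columns must sum to 1 within
$10^{-6}$ (inputs are renormalised); the co-occupancy fractions sum to
1 within $10^{-9}$. Ties are always broken deterministically
(candidate ranking by (chrom, start); nearest gene by identifier).
Degenerate inputs have defined results rather than errors where the
spec of the operation allows: all-zero features ($p = 1$), regions on
gene-less chromosomes (no-neighbour), genes with an all-zero ABC
denominator (all scores 0), loops absent from a sample (count 0).
Chromosome names are compared as exact strings; a suspected naming
mismatch warns rather than silently renaming.

## Limitations

The NB test is not a DESeq2 clone (no empirical-Bayes dispersion, no
LFC shrinkage, no independent filtering, two-group designs only); the
loop background is far simpler than FitHiChIP's; HOMER's motif library
and background construction are not reconstructed; the ABC activity
and Hi-C normalisation conventions of the reference implementation are
under-specified in the source analysis and are replaced by the
transparent conventions above, validated against planted truth. The
headline counts of the original study derive from deep sequencing data
and are not reproducible at this scale; the package's claims are about
the methods' calibration and their recovery of known structure.
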