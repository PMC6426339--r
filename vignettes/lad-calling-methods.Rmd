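---
title: "Calling lamina-associated domains from DamID-seq: models and choices"
author: "LADid package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling lamina-associated domains from DamID-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement

DamID fuses the *E. coli* Dam methylase to Lamin B1 so that DNA contacting
the nuclear lamina acquires adenine methylation (m6A) at GATC motifs.
DpnI cleaves only methylated GATC (bluntly, between A and T: GA^TC);
subsequent DpnII digestion destroys templates still carrying unmethylated
GATC, so only fragments flanked by *two* methylated sites are amplified and
sequenced.  A soluble Dam-only control normalizes for chromatin
accessibility and amplification bias.  The analysis signal is, per genomic
DpnI fragment,

$$ v_f \;=\; \log_2 \frac{(c^{L}_f + p)/T^{L}}{(c^{D}_f + p)/T^{D}} $$

where $c_f$ are fragment read counts, $T$ the per-sample filtered read
totals, and $p$ a pseudocount (default 1 read).  Positive stretches of
$v_f$ are lamina-associated domains (LADs); the intervening negative
stretches are interLADs.

# Coordinate system

`buildFragmentMap()` places a cut at `motif_start + 2` for every GATC and
tiles each chromosome with the resulting intervals (two terminal intervals
included; a GATC-free chromosome is one fragment).  All in-memory intervals
are `GRanges` (1-based closed); every BED/bedGraph interface is 0-based
half-open.  Runs of N produce no motifs, so fragments may span assembly
gaps — gap subtraction at the LAD-calling stage removes them.
`buildBinMap()` provides the constant-size-bin alternative (2–5 kb is a
sensible starting point).

On mouse-like genomes the DpnI map has a median fragment around 260 bp;
on the i.i.d.-uniform genomes the simulator produces, GATC density is
exactly $4^{-4}$ and fragment lengths are geometric with median
$\ln 0.5 / \ln(1 - 1/256) \approx 177$ bp.  The test suite and the
acceptance script assert the latter, computable offline; the former
requires the real genome sequence.

# Read filtering and accounting

`filterAlignments()` drops secondary/supplementary records, unmapped
records, mapping quality below `mapqMin` (default 10 — the
operationalization of "ambiguous locations"), and excluded contigs
(default `chrM`, `MT`, `chrMT`).  The `ContaminationReport` mirrors the
accounting a sequencing table reports: total, unambiguously mapped,
mitochondrial (with percentage of mapped), and post-filter counts.
`qcDepthCheck()` warns below 30 million clean reads, above 26%
mitochondrial contamination (the top of the range observed in primary
hepatocytes), and above 50% unmapped reads (a possible sign of prokaryotic
contamination; mycoplasma must in any case be excluded by PCR before
sequencing).

# Normalization and smoothing

Counting is `overlap` by default (a read increments every fragment it
touches; `midpoint` is available).  Quantile normalization across a set of
ratio profiles uses `limma::normalizeQuantiles(ties = TRUE)` — each rank is
mapped to the across-profile mean of that rank; with a single profile it is
a no-op.  Its scope (within one experiment vs across experiments) is the
caller's choice via `extraProfiles`; across-profiles is the default
behavior when several are supplied.

Smoothing substitutes each value by the mean of a centered window of
`n/2` fragments per side plus the fragment itself (21 values at `n = 20`),
truncated at chromosome boundaries and never crossing them.  Odd `n` is
rounded down with a warning; `n = 0` is the identity.  Smoothing follows
normalization by default; `smoothBeforeNormalize = TRUE` gives the
alternative order, which can also work well.  Because the median fragment
is a few hundred bp, `n = 20` costs only a few kb of boundary resolution
while visibly cleaning noisy interLADs.

# Segmentation

`cbsSegment()` is a from-scratch circular binary segmentation.  Per
chromosome it finds the arc $(i, j]$ maximizing the absolute
pooled-variance two-sample $t$ statistic between the arc and its
complement (arcs may wrap; a wrapping arc is the complement of a plain one
and has the same $|T|$, so scanning $i < j$ covers all of them; ties go to
smallest $i$, then smallest $j$).  Split significance is a permutation
test: the segment's values are permuted `nPerm` times (default 1000) and
the split is accepted when $p = (1 + \#\{T^{max}_{perm} \ge T^{max}_{obs}\})
/ (1 + nPerm) < \alpha$ (default 0.01).  Accepted splits recurse until no
significant split remains or a piece is shorter than twice `minWidth`
(default 2 fragments).

Numerical choices:

* The statistic is computed through centered partial sums: with
  $W_t = S_t - t\bar{x}$, $D = W_j - W_i$, $k = j - i$ and the
  permutation-invariant total sum of squares $C$,
  $T^2 = u / \max((C - u)/(n - 2), 10^{-12})$ with $u = D^2 n / (k(n-k))$.
  $T^2$ is monotone in $u$, so the permutation scan compares $|D|$ against
  a per-width threshold derived once per test, and a range bound on $W$
  rejects most permutations in $O(n)$.  The $10^{-12}$ variance floor keeps
  near-constant arcs finite.
* Segments longer than `permCap` (default 1000) fragments are thinned to
  `permCap` evenly spaced values *for the significance test only*; the
  boundary search always runs at full resolution.  By the time small
  features decide a split, recursion has reduced the segment below the cap.
* The permutation loop stops early as soon as enough exceedances have
  accumulated that non-significance is guaranteed; this does not change
  the decision.
* The "undo splits" pruning of classical CBS implementations is
  deliberately omitted: the LAD post-processing (threshold, merge, minimum
  size) subsumes its role.  On smoothed (hence autocorrelated) profiles
  CBS over-segments; the post-processing absorbs this too.

Given `seed`, segmentation is fully deterministic.

# LAD calling

`callLADs()` applies four steps in a fixed order: subtract assembly gaps
(CBS knows nothing about unsequenced reference stretches, which otherwise
become artifactual LADs), keep segments with mean strictly above `tau`
(default 0; up to 0.1 helps on noisy data), merge regions closer than
`maxGap` (default 5 kb; 5–8 kb works well without fusing distinct LADs),
and drop regions shorter than `minSize` (default 10 kb, inclusive; 5–30 kb
depending on noise).  Boundary semantics the ranges leave open are fixed
and tested: strict `>` at the threshold, `<= maxGap` merges, `>= minSize`
kept.  The parameters used are recorded in the result's provenance.
`compareLADs()` gives the binary presence/absence comparison: base-pair
Jaccard, exclusive coverage, and nearest-boundary offsets.

The pipeline (`runPipeline()`) additionally removes excluded contigs from
the fragment map before profiling: a contig whose reads were all filtered
(e.g. `chrM`) would otherwise carry a constant pseudocount-only profile
whose sign is decided by the ratio of sample totals, and could be called
as an artifactual LAD.

# The simulator

`simulateDamIDExperiment()` emulates the single-cell interpretation of
DamID intensity — the per-fragment probability of lamina contact — rather
than drawing log-ratios directly, so the digestion and amplicon logic is
genuinely exercised and realistic zero-count fragments appear:

1. an i.i.d.-uniform ACGT genome (default 40 Mb over 8 chromosomes) plus a
   16 kb `chrM` contig;
2. non-overlapping LADs with log-uniform lengths in [30 kb, 2 Mb] placed
   until the target coverage (default 0.4) is reached, at least 10 kb
   apart so truth domains stay resolvable; contact probability is high
   inside LADs and `contactOut = 0.1` outside;
3. per-site methylation: each internal GATC site is methylated with the
   mean contact probability of its two flanking fragments (LaminB1-Dam) or
   the accessibility constant 0.5 (Dam-only; an optional dip to 0.3 inside
   LADs models the reduced accessibility of peripheral chromatin);
   a fragment is amplifiable iff both flanking sites are methylated, and
   terminal fragments never are;
4. per-fragment Poisson reads with mean proportional to amplifiability
   times fragment length, uniform read starts (90 bp reads), and
   mitochondrial reads injected binomially at `chrMFraction = 0.15`
   (inside the 7–26% range reported for primary hepatocytes).

The `enrichment` parameter (default 2) sets the in-LAD contact probability
as $\min(1, a\,2^{e/2})$ with $a$ the Dam accessibility, so that the mean
in-LAD log2 ratio equals `enrichment`; setting `contactIn` directly (e.g.
0.9) overrides this.  All stages derive their RNG streams from fixed
offsets of the master seed; outputs are reproducible bit for bit.

**What the simulator does not model.**  Methylation is drawn once per
experiment — a single realization of the cell population average — and
reads are Poisson.  Sequencing error, PCR duplication and per-cell
variability are absent.  Two consequences matter for interpreting green
tests.  First, spurious interLAD positives are a fixed population of
fragments (those whose flanking sites happened to be methylated), so
reducing read depth scales the visibility of signal and noise together:
the count of visible interLAD positives does *not* grow as depth falls,
unlike in real data where PCR and per-cell stochasticity add
depth-dependent noise.  The depth property the model does exhibit — and
the one tested — is graceful degradation: a tenfold depth reduction
worsens boundary recovery and base-pair Jaccard.  Second, "false positive"
counts at the level of *called* LADs are nearly zero at any smoothing on
this clean background, so the smoothing property is asserted on the
profile: the number of interLAD-interior fragments (midpoints more than
15 kb from any truth LAD, excluding `chrM`) with smoothed value above 0.5
is monotone non-increasing over `n` in {0, 10, 20, 100}.  The 0.5 cut
excludes the zero-coverage band: fragments with no reads in either sample
sit exactly at $\log_2(T^D/T^L) \approx 0$, and counting them as signal
would only measure the sign of the total-read ratio.

# Problem sizes and study conditions

The validation suite uses the reference conditions: 40 Mb genome, 40%
LAD coverage, enrichment 2, 2 million reads per sample, smoothing 20 —
about 156,000 DpnI fragments, matching the per-bp read density of a
30–40 M-read mouse experiment.  At these conditions the pipeline recovers
truth with base-pair Jaccard above 0.99 and median boundary offsets under
1 kb (the acceptance script recomputes both).  Smaller genomes (2.5–10 Mb)
are used for unit-level properties.  CBS oracle-equivalence is checked on
500 vectors of length at most 50 with a planted change of four noise
standard deviations, against an independent brute-force scan; null
calibration uses 500 pure-noise chromosomes at $\alpha = 0.05$.

# Known limitations

* Exact numeric agreement with other CBS implementations is not claimed —
  pruning heuristics and p-value approximations differ; behavioral
  agreement (boundary placement, null calibration) is what is tested.
* No GC or mappability correction, no replicate handling beyond quantile
  normalization, no duplicate marking.
* Differential signal-intensity analysis between conditions within sliding
  windows is out of scope; `compareLADs()` implements only the binary
  presence/absence comparison.
* BigWig output is delegated: write bedGraph and convert with
  `wigToBigWig profile.bedGraph chrom.sizes profile.bw`.
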