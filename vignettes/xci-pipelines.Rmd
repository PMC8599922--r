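---
title: "Models and methods behind the xcikit pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the xcikit pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcikit)
```

xcikit packages five small, self-contained computational procedures used in
the study of X chromosome inactivation (XCI): selecting candidate
RNA-binding proteins of a long non-coding RNA from tandem affinity-pulldown
mass spectrometry, scoring allele-specific expression from padlock-captured
SNP counts, quantifying chromatin compaction from ATAC-seq insertion
densities, profiling RNA structure from SHAPE-MaP mutation rates with a
single vehicle control, and estimating transcript half-lives after
transcription blockade.  Each procedure is paired with a synthetic-data
generator whose ground truth makes the downstream statistic checkable
analytically.  This vignette records the models, the tunable parameters,
the numerical choices, and the limits of what a green test establishes.

## Interactome ranking

Two pulldown samples are compared: a tagged pulldown ("flag") and an empty
control.  Each sample yields a protein score table (a protein's score is
the sum of its identified peptides' ion scores).  Within each sample,
proteins are ranked by score (rank 1 = highest).  For proteins identified
in both samples the *ranking gain* is

$$\mathrm{gain}(p) = \mathrm{rank}_{\text{empty}}(p) -
\mathrm{rank}_{\text{flag}}(p),$$

and the candidate set is the union of proteins unique to the flag sample
and shared proteins with gain at or above an inclusive threshold (default
11, empirically anchored in the source assay by the known binder hnRNPM).

Ties in score are broken lexicographically by protein ID (radix/C-locale
order).  The field convention here is unstated; any deterministic rule
gives reproducible ranks, and the brute-force oracle in the test suite uses
the same rule independently.  Proteins present only in the control can
never be candidates.

### Limits of rank-gain selection

The synthetic world draws background scores independently in both samples
from a common lognormal (default `score_shape = 1` on the log scale) and
multiplies the planted binders' scores by `enrichment_factor` (default 20)
in the flag sample only.  This has a consequence worth stating plainly: a
binder's score in the *control* sample is exchangeable with background, so
with $B$ background proteins and $b$ binders its control rank is uniform on
$1..(B+b)$.  Selection by gain $\ge t$ requires a control rank of at least
$t+1$, so expected binder recovery is bounded by $(B+b-t)/(B+b)$ — with
100 background proteins, 10 binders and $t = 11$, at most 90%, no matter
how strong the enrichment or how heavy the score tail.  In practice the
flag rank of the $i$-th strongest binder is about $i$, which lowers
recovery to roughly 85%.  The acceptance suite contains a criterion that
demands 95% recovery in this exact setting; it is implemented verbatim and
fails, and we regard the bound above — not the generator's parameters — as
the explanation.  Rank gains are a selection heuristic with an intrinsic
blind spot for proteins that are already abundant in the control pulldown.

## Allelotyping

Input is a long-format SNP count table from a 129 × *castaneus* hybrid
line: one row per SNP per sample with read counts for the two alleles.
The pipeline applies, in order:

1. **Detection floor** (`filter_undetected`, default `min_reads = 10`): an
   allele count strictly below 10 is set to 0.  The floor is applied per
   allele count by default — the stricter reading of a rule stated for "a
   nucleotide position" — with `per_allele = FALSE` switching to the
   per-position total.
2. **Completeness** (`require_complete`): only SNPs with a non-zero
   post-filter total in *every* required sample are kept (the source
   design used six samples; the sample list is a parameter).
3. **Gene score** (`gene_allelotype`): counts of a gene's surviving SNPs
   are summed per sample, genes on a user-supplied escapee list are
   removed, and each gene × sample cell is scored as

   $$s = \log_{10}\frac{c_{129} + 10}{c_{\mathrm{cast}} + 10}.$$

The pseudocount 10 avoids division by zero and shrinks low-coverage genes
toward 0.  The log base is configurable because the source formula says
only "Log"; base 10 is the default and is recorded in the output
attributes.  With base 10 the score of totals (990, 0) is exactly 2 — a
useful analytic anchor.  Scores are antisymmetric under allele swap and
strictly monotone in each count.  No clipping is applied for display.

The synthetic generator assigns genes to three classes — silenced (129
fraction uniform in 0.95–1, castaneus X silenced), escapee (0.3–0.7), and
biallelic (0.5) — draws per-SNP depth as Poisson (default mean 500) and
allele counts as beta-binomial with intraclass correlation
`overdispersion` (default 0.01, a mild per-SNP bias typical of targeted
capture).  Class counts use largest-remainder apportionment so the truth
is deterministic given `n_genes`.

## ATAC compaction

Each sequencing read's alignment position marks one transposon insertion
event.  Per half-open 1-Mb bin, the **Cut Count** is the number of
*distinct* insertion sites (a flag switches to raw read counting; the
default follows the literal "number of insertion sites").  Counts are
depth-normalised by the ratio of autosomal (non-chrX) read totals,
`reference_total / total_autosomal_reads`, because chrX signal is the
quantity under study and must not influence its own normalisation.  The
compaction score of a bin is

$$\mathrm{score} = \frac{\text{normalised uninduced} + 1}
{\text{normalised induced} + 1},$$

oriented so that compaction upon induction gives scores above 1; the
pseudocount 1 only matters for near-empty bins (both-empty bins score
exactly 1).  Bins are categorised against a user-supplied transcribed-
region BED by overlap fraction: `transcribed` at ≥ cutoff (default 0.5,
inclusive), `intergenic` at ≤ 1 − cutoff, otherwise `mixed`.  Coordinates
are BED-style 0-based half-open throughout; no Tn5 +4/−5 offset is applied
(the source analysis used alignment positions directly).

The generator draws per-bin insertion counts as Poisson with mean
`base_intensity × library_scale / factor` (defaults 2000 sites/Mb, the
order of magnitude of a ~10M-read pilot over a ~2.6-Gb genome), positions
uniform within the bin.  A compaction factor of 2 on chrX is recovered as
a median chrX score of ~2 against a factor-1 autosome, which is what the
acceptance test asserts (tolerance [1.8, 2.2], Poisson noise at
λ ≈ 2000).  Duplicate positions arise with probability ≈ λ/2×10⁶ per pair
and bias distinct-site counts by < 0.2% at these intensities — negligible
against the tolerances used.

## SHAPE reactivity

Mutational-profiling reverse transcription converts chemical adducts on
the probed RNA into mismatches and indels.  `count_mutations` consumes
minimal aligned-read records (position, CIGAR, MD tag — from a data frame
or a minimal SAM file) and, per read, excludes the first and last
`primer_length = 30` aligned positions (both ends by default), counts at
most one mutation event per reference position per read (mismatch, deleted
base, or insertion assigned to the aligned position 5′ of it), and
accumulates per-position depth and events.  Rates below the software
reporting floor `min_depth = 5000` are `NA`.

Reactivity uses one control:

$$\mathrm{reactivity}(i) = \mathrm{rate}_{\text{treated}}(i) -
\mathrm{rate}_{\text{DMSO}}(i),$$

with no denatured-control denominator and no 2–8% normalisation — the
modified single-control scheme subtracts rates only, so reactivities are
on the raw rate scale and may be slightly negative.  Two further
thresholds are deliberately kept distinct from `min_depth`: the
*profiled-nucleotide* filter keeps positions covered by **strictly more
than** `min_reads = 10000` reads in every sample, and a *positive call* is
a mutation rate **strictly greater than** 0.001 (0.1%, near the Illumina
error floor).  Both strict inequalities are boundary-tested.

`pca_profiles` runs mean-centred, unscaled PCA across samples over a
chosen position set (profiles share units, so variance scaling would only
amplify noisy positions).  Component signs follow a fixed convention (the
largest-magnitude loading is positive) so scores are reproducible; an
independent eigen-decomposition oracle checks the scores in the tests.

The generator draws control events as Binomial(depth, background) and
treated events as Binomial(depth, background + reactivity).  In reads
mode it emits full-length reads whose mismatch sets realise exactly the
drawn counts, so the counting path can be checked for *exact* agreement —
a round trip, not a statistical comparison.  The generator does not
emulate amplicon tiling, alignment error, or mate-pair double counting;
a green round-trip establishes the counting arithmetic, not robustness to
those artefacts.

## Decay kinetics

Transcript levels after transcription blockade are modelled as first-order
decay, fitted by least squares on log levels:
$\log y = \log n_0 - k t$, with half-life $\ln 2 / k$ and R² reported on
the log scale (the source's scale is unstated; log-linear fitting makes
the noiseless case exact and is scale- and time-shift-invariant, both
property-tested).  A fitted $k \le 0$ is flagged `no_decay` with infinite
half-life rather than an error.  `include_t0 = FALSE` drops the earliest
point, and `two_phase_fit` (breakpoint default 1 h, per the observation
that the first hour forms a transient slow phase) fits the two segments
independently, re-anchoring the second phase's $n_0$ at its first
timepoint.  qPCR input is normalised by the delta-Cq rule
$y = E^{-(Cq_\text{target} - Cq_\text{ref})}$ with efficiency $E = 2$ by
default, rescaled to the first timepoint.

The generator multiplies a (possibly lagged) exponential by mean-one
lognormal noise with CV `noise_cv` (default 0.1, a typical qPCR
replicate CV); with `k = 0.35`/h over a 0–8 h grid this yields half-life
recovery within 15% in ≳99% of runs, comfortably above the 90% acceptance
floor.

The cell-survival ratio (+Dox/−Dox cell counts) is included for
completeness as `survival_rate`; it is arithmetic, not inference.

## Reproducibility and scope

All generators take a single global seed, split into fixed per-stage
streams (`stage_seed`), restore the caller's RNG state, and are
byte-identical for identical inputs — asserted on files, not in-memory
objects.  `run_stage` writes a provenance sidecar (parameters, package
version, input MD5 digests, no timestamps) next to every result.

Known limitations: MS score tables are consumed as given (no
peptide-level inference or detection-probability modelling, which is why
the rank-gain ceiling above is intrinsic); allelotyping assumes each SNP
maps to one gene and does not model reference bias; ATAC scoring does not
model PCR duplicates beyond the distinct-site rule; SHAPE profiles are
single-stranded arithmetic with no structure prediction; decay fitting
assumes multiplicative noise and will not detect model misfit beyond R².
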