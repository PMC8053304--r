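---
title: "Models and methods behind nucpioneer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucpioneer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpioneer)
```

# The scientific problem

Pioneer transcription factors can engage their binding motifs while the
DNA is still wrapped in a nucleosome, which most transcription factors
cannot. Two complementary experiments probe this ability for p63-class
factors, and `nucpioneer` implements the quantitative analysis of both:

1. **In vitro:** a competitive nucleosome-binding assay. A pool of
   reconstituted nucleosomes, identical except for where a p63 binding
   site sits relative to the nucleosome dyad, is titrated with factor and
   resolved on a native gel. Sequencing the DNA recovered from each gel
   band reveals *which* templates the factor bound, and the position
   dependence locates the boundary inside the nucleosome beyond which
   binding is blocked.
2. **In vivo:** summit-centered chromatin profiling. Around factor
   ChIP-seq summits, histone-mark, accessibility and nucleosome-occupancy
   tracks are binned, standardized and clustered to ask what chromatin
   the factor binds into and what changes after it binds.

Raw sequencing data are deliberately out of scope: a seeded synthetic-data
module generates inputs with exactly the statistical structure the
analysis assumes, so every stage is testable on a desk.

# Template library design

Templates are built on a Widom 601 positioning backbone: the canonical
147-bp core (`widom601_core()`) flanked by 35 bp on each side, giving a
217-bp construct whose dyad sits at 0-based index 108. The flank
sequences shipped with the package are synthetic, designed so the 3'
flank carries a single CATG half-site core just outside the positioning
core; the exact flanks of the original constructs are not part of the
published text, and any real construct set can be loaded with
`read_library_fasta()`.

A 20-bp motif — either the high-affinity ideal site
`GGGCATGTCCGGGCATGTCC` or the natural intermediate-affinity *CDKN1A*
promoter site `AGACTGGGCATGTCTGGGCA` — is substituted into the backbone
with its **center** placed 0, 5, 41, 46, 66, 71 or 81 bp 3' of the dyad.
The published design does not state whether offsets are measured to the
motif center or its proximal edge; the center convention is used because
it keeps the two motif kinds directly comparable and keeps every
placement inside the 217-bp template (81 + 10 < 109). Two motif-free
controls complete the 16-template library: the unmodified backbone
(`601`) and a modified control (`601M`) in which every CATG lying wholly
outside the positioning core is rewritten to AGGT, removing spurious
half-sites from the flanks while leaving the core untouched.

The superhelix location (SHL) of a placement is its dyad offset in
helical turns, `round(offset / period * 2) / 2` with ties away from
zero. The default period of 10.2 bp/turn reproduces the printed labels:

```{r shl}
vapply(c(0, 5, 41, 46, 66, 71, 81),
       function(d) assign_shl(d)$label, character(1))
```

Offsets beyond the 73-bp core half-width lie in the linker and carry a
linker flag (offset 81 is "SHL 8, linker"). Offsets paired 5 bp apart
(0/5, 41/46, 66/71) differ by roughly half a helical turn, i.e. the
motif faces the histone octamer on opposite rotational phases.

# EMSA-seq quantification

## The relative-shift statistic

Reads excised from each band are assigned back to templates and counted.
For template $N$, with nucleosome-band counts $c$ and input-lane counts
$i$, relative to the non-specific control template (601 by default, 601M
supported),

$$\mathrm{RS}_N \;=\; -\log_2\!\left(
  \frac{c_N / c_{\mathrm{601}}}{i_N / i_{\mathrm{601}}}\right).$$

Templates preferentially bound (and therefore supershifted out of the
unshifted band) are depleted from $c$ and score positive. Because the
statistic is a ratio of ratios it is invariant to any per-band or
per-lane depth rescaling — exactly the technical variability
(gel excision, PCR, library construction, sequencing depth) it is built
to cancel. A pseudocount (default 0.5) guards sparse bands; the
reference's value is identically 0. The supershift-band analogue drops
the leading minus sign, so bound templates score positive there too, and
multiple supershift bands are pooled into one shifted class before the
computation.

## Read assignment

Templates differ from one another by a 20-bp substitution block (or a
few flank edits), never by indels, so assignment uses a best
ungapped-offset Hamming scan over both strands (the one compiled hot
loop in the package). A read is counted for the unique template with the
minimal mismatch count; reads tied between templates or worse than
10% mismatches are tallied as unassigned. Because gel bands contain the
intact 217-bp construct, simulated paired reads sequence both ends of
the full fragment (2 x 150 bp), jointly covering every position — this
makes error-free assignment an exact inverse of the count table, which
the tests exploit. Single-end reads that do not reach a distinguishing
position are *legitimately* ambiguous and land in `unassigned`.

## The positional-accessibility binding model

Occupancy of template $N$ at factor concentration $c$ is modelled as

$$\theta_N = \theta_0 + (1-\theta_0)\,\frac{c}{c + K_d / a(d)},
\qquad a(d) = \frac{1}{1 + e^{-(d - d^\*)/s}},$$

with $K_d$ the motif's dissociation constant on accessible DNA,
$\theta_0$ a non-specific bound fraction, and $a(d)$ a logistic
accessibility switch at distance $d$ from the dyad: sites near the dyad
are occluded, sites near the entry/exit edge become accessible through
partial unwrapping. $a(d^\*) = 1/2$ exactly; $s$ sets the boundary
sharpness in bp. Motif-free controls sit at $\theta_0$.

The expected relative shift has a closed form that the fit exploits:

$$E[\mathrm{RS}_N] = -\log_2\frac{1-\theta_N}{1-\theta_{\mathrm{ref}}}
 = \log_2\!\left(1 + \frac{c\,a(d)}{K_d}\right),$$

notably independent of $\theta_0$ (which is therefore not identifiable
from shifts and is reported as 0 by the fit). `fit_positional_model()`
minimizes least squares over a coarse grid ($d^\*$ 0–90 bp in 2-bp
steps; $s \in \{1,2,4,8\}$ bp; log-spaced $K_d$, optimized separately
per motif kind since the residual decomposes) followed by Nelder–Mead
refinement. The objective is deterministic; no seed is involved. If no
motif template shows a mean |shift| above the noise floor (default 0.1
log2 units) the fit declines to estimate and returns a no-binding flag.

## Simulation conditions

`emsa_sim_config()` defaults encode the published assay conditions: five
lanes at 18, 36, 71, 142 and 286 nM factor plus an input lane; uniform
input frequencies over the 16 templates; 2 x 150 bp paired reads. The
ground-truth model defaults ($K_d^{\mathrm{high}} = 25$ nM,
$K_d^{\mathrm{int}} = 100$ nM, $\theta_0 = 0.02$, $d^\* = 50$ bp,
$s = 2$ bp) put the boundary at the published 50 bp inhibition distance,
give edge templates strong shifts within the titrated concentration
range, and keep dyad templates at control level — the qualitative
pattern of the assay. Band counts are multinomial: nucleosome-band
weights $\propto f_N(1-\theta_N)$, supershift weights
$\propto f_N\theta_N$, input weights $\propto f_N$, each at a configured
depth (10^6 in the acceptance runs, which makes the Monte-Carlo standard
error of a shift value about 0.01 log2 units). What this generator does
*not* model: MNase/fragmentation bias, PCR duplication structure,
gel-band cross-contamination, or more than one supershift stratum.
Passing tests therefore validate the estimator and its invariances, not
those artefacts.

# Summit-centered chromatin profiling

## Profile matrices

`binned_profile()` sums per-base coverage in 10-bp bins across a 2-kb
window centered on each summit and rescales by
`standard_total / total_tags` — a standardized tag count, 10^8 for
histone marks and 10^9 for nucleosome occupancy by convention. Windows
running past a chromosome end are dropped with a warning. Scaling a
track by any positive constant leaves the matrix unchanged, which is
the property the feature step relies on.

## Grouping, accessibility, annotation, comparison

Sites are grouped by k-means (default k = 4, 100 seeded restarts, best
within-cluster sum of squares kept, labels ordered by descending size)
on one feature per mark: `log2(1 + mean standardized window signal)`,
z-scored per mark. Summary features rather than full 200-bin vectors
were chosen as the default because at a few hundred sites they are
substantially more stable under noise and make the group structure
directly interpretable; the profile matrix itself is available to
cluster on if desired. Accessibility is a summit-in-interval call
against an accessible-interval BED (half-open on disk). Annotation
precedence is promoter (stranded TSS −1000/+100, approximating common
peak-annotator defaults) > exon > intron > intergenic, and the four
fractions sum to 1. Two summit sets are compared by matching summits
within 100 bp (the published partition's rule is not stated; 100 bp is
of the order of a peak half-width), partitioning each set exactly once.

## Nucleosome symmetry

Occupancy profiles around summits are aligned in the restricted mode
the study used: 0-bp shifts with region reversal enabled. Each site may
be used forward or bin-reversed and is assigned jointly to the
(cluster, orientation) minimizing Euclidean distance to the cluster
mean; means are recomputed from oriented members until assignments
stabilize (20 seeded restarts, best objective kept; orientation ties
break to forward). The objective is non-increasing by construction.
One subtlety is a gauge freedom: mirroring every input row yields the
same solution encoded with mirrored means and unchanged orientation
labels, since reversing both a row and its mean preserves their
distance. Tests assert the invariant up to that gauge. The peak of an
oriented cluster-mean profile, `occupancy_peak_offset()`, measures how
far the positioned nucleosome's dyad sits from the binding site — the
generator plants 50–60 bp and the round trip recovers it to within one
10-bp bin.

## Acetylation change

`signal_delta()` reports the per-bin difference of average profiles
(after − before) and a peak–valley–peak call on the after profile: the
central ±100 bp must hold the local minimum and both flanks must carry
a maximum within ±500 bp exceeding the valley by a factor of 1.25
(configurable; 1.25 comfortably separates a genuine flanking-nucleosome
gain from flat elevation while tolerating bin noise). Because profiles
are depth-standardized, a track-wide rescaling produces a flat, shape-
free offset at unaffected sites — the flag, not a zero delta, is the
meaningful readout there.

## The synthetic genome

`chromatin_sim_config()` plants, on two small chromosomes (500 + 350
kb), 250 summits in four groups mirroring the observed classes: three
minority active classes — promoter-like (H3K4me3/H3K9ac-high),
enhancer-like (H3K4me1/H3K27ac-high), repressive
(H3K9me3/H3K27me3-high) — and a majority class (160/250, 64%; the study
found 81%) with background-only marks, mirroring the finding that most
induced binding sites are bereft of histone modifications. The
accessible fraction defaults to 0.28 (the study's 551/1980); accessible
intervals are assigned in group order so the unmodified class is
inaccessible. Every site carries a positioned nucleosome whose dyad is
displaced 50–60 bp from the summit on a random side, and the
after-induction H3K27ac track adds flanking gains (Gaussians at ±200
bp) with the central valley at bound sites. A second cell line shares
120 sites (jittered ±20 bp) plus 40 unique ones for the set-comparison
stage. Signal shapes are sums of Gaussian bumps on a constant
background; `noise` interpolates each 10-bp bin toward a Poisson draw
of its expected tag sum (0 = exact expectation, used wherever a test
asserts an exact closed loop). Real chromatin differs in ways the
generator does not attempt: irregular peak shapes, copy-number and
mappability artefacts, correlated marks, and diffuse domains — so green
tests certify the pipeline's logic, not robustness to those.

# Numerical and design choices

- **Coordinates.** On disk, BED/bedGraph are 0-based half-open as their
  formats require; in memory the package follows Bioconductor's 1-based
  closed `GRanges` convention. Sequence design arithmetic is stated
  0-based (dyad index 108 of 217) to match the construct definition.
- **SHL rounding** is to the nearest half turn with ties away from
  zero; 10.2 bp/turn reproduces the published labels 6.5/7/8 for
  offsets 66/71/81, where 10.0 would not (66/10 = 6.6 rounds to 6.5,
  but 71/10 = 7.1 rounds to 7 and 81/10 = 8.1 rounds to 8 — the period
  matters for larger offsets under different conventions).
- **Ties.** Read assignment: tie between templates → unassigned.
  Orientation: tie → forward. Peak offset: tie → smallest |offset|.
  k-means label ties are resolved by original label order.
- **Degenerate inputs.** Zero-weight multinomial bands return zero
  counts; all-zero occupancy profiles return an undefined-peak flag;
  zero-variance marks skip z-scoring with a warning; an all-zero shift
  table returns a no-binding flag rather than estimates.
- **Problem sizes.** Acceptance-level runs use band depth 10^6 and the
  250-site synthetic genome above; unit tests run smaller replicas of
  the same constructions. These sizes were chosen so Monte-Carlo error
  is far below every asserted tolerance while a full run stays
  desk-scale.
- **Replicates** are aggregated by arithmetic mean with the range
  reported alongside, matching how duplicate titrations are presented
  and fitted.

# Known limitations

- The binding model is a single-site occupancy isotherm; cooperative
  multi-factor binding (the likely source of multiple supershift bands)
  is collapsed into one shifted class.
- $\theta_0$ cancels from relative shifts, so only $K_d$, $d^\*$ and
  $s$ are estimable from shift curves; absolute occupancies would need
  band-intensity data the assay does not quantify.
- The annotator is a simplified precedence classifier, not a full
  transcript-model annotator; the promoter window is fixed, not
  expression-aware.
- `fit_positional_model()` estimates are only as localized as the
  offset design allows: with the default seven offsets the data
  constrain $d^\*$ through the 41/46/66 transition, so boundaries far
  outside that range are reported at reduced precision.
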