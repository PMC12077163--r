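---
title: "Resolving velvet-domain architecture from column conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving velvet-domain architecture from column conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velvetarch)
```

## The problem

Velvet proteins are fungal transcription factors with an NF-κB-like fold
that regulate development and secondary metabolism through homo- and
heterodimerization (the *Aspergillus nidulans* quartet VeA, VelB, VelC and
VosA is the best-studied case). Their shared velvet domain has a canonical
layout: an N-terminal DNA-binding region of roughly 30 alignment columns, a
connector of wildly variable length, and a C-terminal dimerization region
of roughly 100 columns that splits into an α-subunit and a β-subunit
separated by a flexible linker. `velvetarch` reconstructs this layout from
a domain collection: it aligns domains to a profile built from a seed
alignment, scores per-column conservation, segments the conservation track
into the five regions, tabulates per-sequence region lengths, and turns the
most conserved columns into an alanine-scanning plan expressed in a
reference protein's residue numbering (e.g. VelB G240/L331 and their VosA
and VeA counterparts). A small structure module checks dimer-interface
residue contacts in a complex coordinate file.

## The conservation model

For every match column $c$ with residue distribution $p_c$ and background
$q$, the conservation score is the Jensen–Shannon divergence

$$\mathrm{JSD}(p_c, q) = \lambda\,\mathrm{KL}(p_c \,\|\, m) +
  (1-\lambda)\,\mathrm{KL}(q \,\|\, m), \qquad
  m = \lambda p_c + (1-\lambda) q,$$

with logarithms base 2 and $\lambda = 1/2$, so the score is symmetric and
bounded in $[0, 1]$. Three post-processing steps follow the common
conventions of this scoring method:

* **Gap penalty.** The raw score is multiplied by $1 - g_c$, where $g_c$ is
  the fraction of gap (or `X`) rows; heavily gapped columns cannot rank as
  conserved no matter how skewed their few residues are.
* **Window smoothing.** Each penalized score is blended with its flanks:
  $s'_i = (1-\lambda_w) s_i + \lambda_w \sum_{j \in W_i} s_j / (2w)$ with
  $w = 3$ columns per side and $\lambda_w = 1/2$, self excluded. The
  flanking sum is always divided by the full $2w$; columns at the track
  ends, which lack part of their window, are therefore pulled toward zero.
  We chose this zero-padded form because segmentation benefits from
  conservative scores at the profile edges; `pad = "truncate"` selects the
  alternative that makes constant tracks exact fixed points everywhere.
* **Information content.** Independently of the JSD track, each column gets
  a sequence-logo information content $\log_2 20 - H(p_c)$ in bits, with an
  optional small-sample correction $19/(2 n \ln 2)$. The correction is off
  by default: the conserved-residue call ("bits over 2") targets
  survey-scale alignments where the correction is of order $10^{-3}$ bits.

The background $q$ defaults to uniform over the 20 amino acids; a BLOSUM62
marginal background is selectable (`aa_background("blosum62")`) and the
choice is recorded in the run configuration. Sequence weighting
(position-based Henikoff weights) is off by default and available as an
option; both choices are reported in output metadata because survey
analyses differ in these conventions.

## Profile alignment

The aligner is a position-specific log-odds profile with affine gaps — the
desk-scale counterpart of a profile-HMM aligner, sufficient for assigning
match columns when domains have already been excised. Column frequencies
are estimated from a seed alignment with a background-proportional
pseudocount,

$$\hat f_{c,a} = \frac{n_{c,a} + \tau q_a}{n_c + \tau},$$

scored as $\log_2(\hat f_{c,a}/q_a)$ bits, and aligned
global-in-profile/global-in-sequence by dynamic programming (Rcpp). A gap
of length $k$ costs $\text{open} + (k-1)\,\text{extend}$, with defaults
4 and 0.25 bits shared by insertions and deletions — a deliberate
simplification of state-specific HMM transition probabilities, recorded in
the configuration. Ties break deterministically (match > delete > insert).
`X` scores 0 bits everywhere. There is no E-value machinery: database
score calibration only makes sense against a genome-scale sequence
collection, so homolog screening is exposed as a bit-score threshold
(`score_filter()`) instead.

## Segmentation

`segment_regions()` thresholds the smoothed, gap-penalized JSD track at the
midpoint between its 20th and 80th percentiles, merges above-threshold runs
separated by fewer than 5 columns, and drops runs shorter than 10 columns.
Exactly two super-blocks are expected: DNA-binding (N-terminal) and
dimerization (C-terminal), with the span between them labeled variable.
Inside the dimerization block the same percentile rule, applied to the
block's own scores, identifies internal valleys at least 5 columns wide;
the lowest-scoring one is the linker, and what flanks it becomes α and β.
Any other block count raises a condition object carrying the detected run
list, and a user-supplied template always overrides inference — so a
published, figure-derived architecture can be imposed directly.

These defaults are tuned to the velvet signal shape: the percentile
midpoint separates the two conservation regimes without assuming absolute
score levels, and the 5-column merge gap absorbs single-column dropouts
without bridging a genuine linker valley (which is wider by construction).

## Region lengths

Lengths are measured on the ungapped sequence: match-state occupancies
inside a region plus insert-state residues anchored between its columns.
This insert-inclusive definition is the only one that can reproduce
variable regions beyond 400 aa against a fixed ~200-column profile. An
insert run anchored exactly at a region boundary is attached to the region
owning the left flanking column (runs before column 1 belong to the first
region); the generator and the aligner never anchor runs at region
boundaries, so the convention only matters for hand-built alignments.
Range statistics ("share of sequences with variable region of 40–60 aa")
use inclusive endpoints, while histogram bins are left-closed/right-open;
both conventions are embedded in the run metadata.

## The synthetic generator

`sample_family()` draws families with a planted, fully known architecture
so that every downstream stage can be tested against exact truth. Defaults
emulate a fungal-kingdom velvet survey:

| feature | default | rationale |
|---|---|---|
| match columns | 30 + 60 + 45 + 20 + 40 | canonical ~30-column DNA-binding and ~100-column dimerization blocks |
| variable-region length | 0–450 aa, atom at 0, log-normal body (mode ≈ 50), exponential tail; mass in [40, 60] = 0.47 exactly | connectors range from absent to >400 aa with the largest group at 40–60 aa (47% of sequences) |
| linker length | 5–60 aa, normal body centred at 20; mass in [15, 25] = 0.63 exactly | linker lengths concentrate in 15–25 aa (63% of sequences) |
| column conservation | per-class Dirichlet: conserved blocks dominance 0.90, linker 0.75, variable 0.00 (concentration 60) | two conservation regimes with the linker as an internal valley of the dimerization block, clearly above variable-region background |
| invariant sites | G at 98% identity (α), L at 95% (β) | the family's hallmark glycine/leucine pair |

The length samplers are calibrated by exact reweighting: a base mixture
fixes the shape, then mass inside vs outside the target range is rescaled
so the printed survey fractions hold by construction. Only the masses are
treated as data; the shapes (log-normal body, exponential tail) are the
package's own modelling choice, since the full empirical histograms are
not published.

The linker dominance (0.75) sits deliberately between the conserved blocks
(0.90) and the variable background (0.00) but nearer the blocks: the
dimerization region is conserved *as a whole*, and the linker must stay
above the global conserved/variable threshold while forming the
within-block valley. A markedly lower value turns the linker into a second
variable region and the domain into three blocks, which is not the biology
being emulated.

What the generator does **not** model: phylogenetic correlation between
sequences (columns are exchangeable given their class; there is no tree),
taxon-specific length regimes (e.g. the concentration of very long
connectors in particular lineages), compositional biases, or alignment
error in the input. Passing tests on synthetic families therefore
demonstrate correctness of the machinery under known truth — not that a
real survey's numbers are insensitive to alignment choices; dataset-wide
reproduction additionally depends on the aligner matching the original
profile-HMM column assignment.

Realizing a sampled length against fixed match columns deletes a random
column subset (when short) or adds one insert run at a random internal
anchor (when long); conserved blocks are insertion-free and fully
occupied. All sampling flows from one integer seed; the caller's RNG state
is saved and restored.

## Numerical and degenerate-input choices

* All-gap columns are flagged, score 0, and are excluded from logo heights.
* Distributions are validated to sum to 1 within $10^{-9}$.
* Conserved-column calls use *strictly greater than* the bits threshold.
* `span_length()` and all spans are 1-based inclusive ("positions 280–310"
  is 31 residues); column indices are 1-based.
* A hydrogen bond is operationalized as the minimum distance between polar
  heavy atoms (N, O; backbone included, since glycine has no side chain) —
  no hydrogen placement or angle criterion, matching a single printed
  distance. Reported to one decimal with the raw value attached.
* Structure parsing uses the first model, drops waters and hydrogens, and
  resolves alternate locations to the highest-occupancy copy.

## Problem sizes

The test-suite and acceptance runs use n = 200 families (5 replicates) for
architecture recovery and one n = 5,000 family for survey-scale length and
identity statistics — the same order as the published 4,999-domain survey —
with profile length ~195 columns. A full pipeline run at n = 200 takes
about a second; the n = 5,000 statistics a few seconds.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(list(seed = 3, synthetic = list(n_sequences = 200)))
res$template
#> <architecture_template> (inferred)
#>   dna_binding  cols    1-  30 (30)
#>   variable     cols   31-  90 (60)
#>   alpha        cols   91- 133 (43)
#>   linker       cols  134- 156 (23)
#>   beta         cols  157- 195 (39)
res$summary$variable_percent_in_range   # 48
res$summary$linker_percent_in_range    # 59
```

## Known limitations

* The profile aligner is glocal-only, with shared insert/delete penalties;
  column assignments can differ from a full profile HMM near block edges,
  which is why dataset-wide statistics are flagged as alignment-sensitive.
* Segmentation assumes the two-block velvet signal; domains with different
  architectures need a user-supplied template.
* The exact column spans delimiting "variable region" and "linker" in the
  published survey statistics are not printed; reproduction of those
  fractions is boundary-sensitive at the ±1–2 column level.
* No graphical logo rendering — numeric letter-height matrices only.
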