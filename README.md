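# velvetarch

Resolving the architecture of fungal **velvet domains** — the DNA-binding /
dimerization domain that defines the VeA / VelB / VelC / VosA family of
NF-κB-like fungal regulators — from large domain collections.

Velvet domains share a canonical layout: an N-terminal DNA-binding region
(~30 alignment columns), a connector whose length varies from 0 to more
than 400 residues, and a C-terminal dimerization region (~100 columns)
built from an α-subunit and a β-subunit around a flexible linker.
`velvetarch` reconstructs that layout computationally:

* **Profile alignment** — build a position-specific log-odds profile (bits)
  from a seed alignment and align domain sequences to it with an
  affine-gap dynamic program (`build_profile()`, `align_family()`,
  `score_filter()`); match/insert bookkeeping follows the Stockholm
  `#=GC RF` / aligned-FASTA case conventions (`read_alignment()`).
* **Conservation scoring** — per-column Jensen–Shannon divergence against a
  background, `JSD(p, q) = λ KL(p‖m) + (1−λ) KL(q‖m)` with `m = λp +
  (1−λ)q` (base-2, λ = 1/2), gap-penalized by `1 − gap_fraction` and
  window-smoothed; plus sequence-logo information content
  `log2(20) − H(p)` in bits (`conservation_profile()`, `logo_matrix()`).
* **Architecture segmentation** — threshold the smoothed track, find the
  two conserved super-blocks, and split the dimerization block at its
  internal valley into α / linker / β (`segment_regions()`); per-sequence
  region lengths include insert-state residues, so 400-residue connectors
  are measured correctly (`region_lengths()`, `length_distribution()`).
* **Alanine-scan planning** — columns above a bits threshold (default:
  bits > 2), mapped to a reference protein's residue numbering
  (`plan_alanine_scan()`), with cross-protein correspondence tables
  (`correspondence_table()`) of the kind that links VelB G240/L331 to
  VosA G96/L171 and VeA G83/I180.
* **Structure contacts** — read a dimer complex (PDB/mmCIF) and measure
  polar heavy-atom distances between interface residues
  (`min_polar_distance()`, `interface_contacts()`).
* **Synthetic families** — a generator with planted, fully known
  architecture and conservation (`family_spec()`, `sample_family()`) so
  every stage is testable against exact truth; its defaults emulate a
  fungal-kingdom velvet survey (47% of connectors in 40–60 aa, 63% of
  linkers in 15–25 aa, near-invariant G/L hallmark sites at 98%/95%).

## A worked example

```r
library(velvetarch)

res <- run_pipeline(list(seed = 3, synthetic = list(n_sequences = 200)))

res$template
#> <architecture_template> (inferred)
#>   dna_binding  cols    1-  30 (30)
#>   variable     cols   31-  90 (60)
#>   alpha        cols   91- 133 (43)
#>   linker       cols  134- 156 (23)
#>   beta         cols  157- 195 (39)
```

The pipeline sampled a 200-member family with planted architecture
30 / 60 / 45–20–40, re-aligned the unaligned sequences to a profile,
scored conservation, and recovered every planted boundary within two
columns. The summary carries the survey statistics:

```r
res$summary$variable_percent_in_range
#> [1] 48        # share of sequences with a 40-60 aa variable region
res$summary$linker_percent_in_range
#> [1] 59        # share with a 15-25 aa linker
head(res$summary$scan_residues)
#> [1] 86 87 88 89 90 91   # residues proposed for alanine substitution
```

Percentages are reported with raw fractions attached
(`res$distributions$variable$fraction_in_range`), and all outputs
(conservation track, logo matrix, architecture, lengths, scan plan,
summary JSON) are written as TSV/JSON when `output_dir` is set.

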