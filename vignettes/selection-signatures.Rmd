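---
title: "Scanning for selection signatures with iHS and runs of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for selection signatures with iHS and runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoofprint)
```

## The problem

Sustained artificial selection in livestock — for milk yield, fertility,
disease resistance, heat tolerance — leaves localized distortions in the
pattern of genomic variation. `hoofprint` implements two complementary
haplotype- and genotype-based scans for such footprints in dense diploid
panels (hundreds to thousands of animals, tens of thousands to hundreds of
thousands of autosomal SNPs), together with the simulator needed to verify
every stage at desk scale:

* the **integrated haplotype score (iHS)**, which detects alleles that have
  risen to intermediate frequency so recently that recombination has not yet
  shortened the long haplotype they ride on; and
* **runs of homozygosity (ROH)**, stretches of consecutive homozygous
  genotypes created by autozygosity, whose population-level clustering
  (**ROH islands**) marks shared selection or founder effects.

Genomic inbreeding coefficients and interval annotation against gene, QTL
and eQTL tables complete the pipeline.

## The iHS scan

### EHH

For a core SNP and core allele, the extended haplotype homozygosity at a
marker $x$ is the probability that two randomly drawn carrier haplotypes are
identical over the closed interval between the core and $x$:

$$EHH(x) = \frac{\#\{\text{identical carrier pairs over } [core, x]\}}
               {\binom{n_{carriers}}{2}}.$$

The denominator is fixed at the core; a haplotype that hits a missing call
is removed from the numerator from that marker outward. Both choices make
the decay provably non-increasing, which the test suite asserts on every
computed curve. `compute_ehh()` returns the full decay grid;
`compute_ihh()` integrates it.

### iHH and truncation

iHH is the trapezoidal integral of EHH over physical distance (bp), summed
over the two sides of the core. Two truncation rules bound the integral,
and both are deliberately conservative because the source studies leave
them unstated:

* each side stops at the *last marker with EHH ≥ `ehh_cutoff`* (default
  0.05) — the segment that crosses below the cutoff is excluded;
* a side that meets an inter-marker gap larger than `max_gap_bp` (default
  200 kb) stops at the near edge of the gap, so sparse map regions cannot
  inflate the integral.

A single-marker side contributes zero. Distances are physical only; no
genetic map is used, matching how such scans report regions in cattle.

### Standardization

The raw score $\ln(iHH_A/iHH_D)$ (A = ancestral, D = derived) is
standardized to mean 0, SD 1 within derived-allele-frequency bins,
because unselected low-frequency derived alleles sit on systematically
longer haplotypes. Ancestral state is assigned as the dataset-wide majority
allele; exact 50/50 ties fall to the reference allele, are flagged, and are
excluded from the bins. Defaults: bin width 0.05 (20 bins on (0,1)),
minimum bin membership 10 (smaller bins are flagged, not standardized),
minimum derived frequency 0.05, and the sample ($n-1$) standard deviation —
chosen for unbiasedness in small bins and mirrored exactly by the test
oracles. All are exposed as arguments.

### Windows and candidate regions

`scan_windows()` tiles each chromosome with 500-kb windows stepped every
250 kb (half-width overlap) and scores each window by the mean
$|iHS|$ of its SNPs; windows with fewer than 3 scored SNPs are excluded
from the empirical distribution. Candidates are the top 1% of windows by
the nearest-rank rule with ties included; a fixed cutoff (e.g. $|iHS| > 2$)
is available as an alternative mode because published scans use both
conventions. `merge_candidate_windows()` unions overlapping or adjacent
candidates into maximal regions.

A genuine sweep spreads extreme scores over the whole shared-haplotype
halo, so the argmax window lands anywhere on that plateau rather than
always on the window containing the focal SNP. The sweep-recovery check is
therefore defined as: *the top-ranked window overlaps the true swept
interval* — the localization claim a practitioner actually relies on.

## The ROH detector

`detect_roh()` reproduces the PLINK `--homozyg` sliding-window logic with
the parameter set standard for dense cattle panels:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 100 | SNPs per sliding window |
| `max_het_per_window` | 1 | tolerated heterozygotes per window |
| `max_missing_per_window` | 5 | tolerated missing calls per window |
| `hit_proportion_threshold` | 0.05 | min fraction of homozygous windows covering a SNP |
| `max_gap_bp` | 100,000 | split runs at larger inter-SNP gaps |
| `min_length_bp` | 1,000,000 | strict: segments must be longer |
| `min_snps_per_segment` | 100 | minimum SNPs per segment |
| `min_density_bp_per_snp` | 50,000 | at least one SNP per 50 kb |

One behaviour needed a decision the sliding-window description does not
determine. The permissive 0.05 hit-proportion rule lets qualifying runs
bleed a few SNPs into heterozygous flanking sequence; applied naively, a
segment-level one-het limit would then discard long genuine tracts because
of flanking noise. `detect_roh()` instead trims runs to homozygous
non-missing endpoints and, where more than one heterozygote remains,
decomposes the run into its maximal subsegments containing at most one
heterozygous call (longest span first, deterministic), before applying the
length, SNP-count and density filters. This honours both the one-het
tolerance (meant to absorb a single genotyping error in an otherwise
autozygous tract) and the intent that long tracts not be lost to edge
effects; truth-tract recovery on simulated data moves from ~87% to ~91% of
base pairs with no change to any threshold. Segment boundaries are the
first and last member SNP positions; length is `end − start` everywhere in
the package, so a region printed as 39,852,457–41,196,648 has length
1,344,191 bp.

`classify_and_summarize()` bins segments into the left-closed classes
[1,2), [2,4), [4,8), [8,∞) Mb and reports counts, percentages (rounded to
integers in reports), mean/SD lengths and genome-coverage percentages;
`roh_class_totals()` recomputes the totals, count-weighted mean and summed
coverage from class-level statistics alone, which is how the published
class table can be checked for internal consistency without the underlying
genotypes.

### ROH islands

`snp_incidence()` computes, per SNP, the fraction of individuals with at
least one covering segment (overlapping segments of one animal count
once). `call_islands()` selects the top 1% of SNPs by incidence
(nearest-rank, ties included) and merges runs of consecutive selected SNPs
into islands; islands are kept when every member SNP exceeds the 30%
occurrence floor — implemented as a post-filter that can be disabled, since
the floor could equally be read as an observed property of top-1% SNPs —
and when they contain at least `min_snps` SNPs (default 5; published
islands carry 29–134 SNPs, and a small floor suppresses single-SNP
artifacts). No bridging across below-threshold SNPs is done by default
(`bridge_gap = 0`), with a configurable gap for sensitivity analysis.

## Inbreeding coefficients

`compute_ibc()` reports the three SNP-based estimators familiar from
GCTA's `--ibc`: the GRM-diagonal form $F_{GRM}$, excess homozygosity
$F_{HOM}$, and the uniting-gametes correlation $F_{UNI}$ (formulas in the
function documentation). Allele frequencies come from the analyzed sample
itself, monomorphic sites are excluded, and missing dosages are skipped
with per-individual SNP counts. Both fully heterozygous and fully
homozygous individuals at $p = 0.5$ evaluate to exactly $-1$ and $+1$ on
all three estimators, which the tests pin down by hand-derived algebra.

## The synthetic-data generator

`simulate_neutral()` builds haplotypes as first-order mosaics of founder
haplotypes: at each SNP step the copied founder is redrawn uniformly with
probability `recombination_switch_prob`. Defaults emulate the structure of
a dense reduced-representation cattle panel at desk scale:

* 200 diploids × 10,000 SNPs on a 150-Mb chromosome — mean marker spacing
  15 kb, matching the ~15.6-kb spacing of the motivating panel, with
  irregular spacing from sorted uniform position draws;
* 20 founders and switch probability 0.01 per step, giving haplotype
  blocks of roughly 100 SNPs (~1.5 Mb);
* a uniform MAF spectrum on [0.05, 0.5], the post-QC range;
* genotype error 0.001 per call and missingness 0.01 — the error level the
  one-het ROH allowance is designed to absorb;
* autozygosity tracts as a Poisson process (2 × 10⁻⁸ starts/bp per
  individual, ≈ 3 tracts per individual per chromosome) with
  exponential lengths of mean 2 Mb;
* optionally, a partial hard sweep: a deterministic fraction β (default
  0.5) of haplotypes receives the derived allele at the focal SNP plus one
  identical template haplotype across a halo whose total span is
  `halo_bp` (default 2 Mb, half to each side); everything else is
  untouched.

Every stage consumes one RNG stream seeded once per run, so whole runs are
bit-reproducible. What the generator does **not** emulate: coalescent
genealogies, recombination-map heterogeneity, demographic history,
ascertainment bias of the genotyping assay, and linkage between the sweep
and background LD beyond the copied halo. Passing recovery tests therefore
demonstrate that the statistics behave as designed under their own model
assumptions — not that real cattle data are free of those complications.

## Verification strategy and problem sizes

* EHH equals a brute-force pairwise-identity enumeration exactly on random
  panels up to 20 haplotypes × 15 SNPs; the windowed scan's per-SNP
  integrals equal `compute_ehh()` + `compute_ihh()` composed.
* Standardized iHS is calibrated (|bin mean| < 0.05, |bin SD − 1| < 0.05)
  on a neutral panel of 1,000 haplotypes × 20,000 SNPs on 300 Mb.
* The sweep scan localizes the swept interval in ≥ 19 of 20 seeded
  replicates at β = 0.5 with a 2-Mb halo (200 diploids × 10,000 SNPs).
* `detect_roh()` matches an exhaustive loop-based reference exactly on 200
  random panels of ≤ 300 SNPs (window scaled to 20 SNPs so segments occur
  at that panel size), and recovers ≥ 90% of forced-tract base pairs from
  tracts ≥ 1.5 Mb across 6 replicates of 100 diploids × 10,000 SNPs at
  error rate 0.001.
* A tract forced into every individual is contained in a called island in
  10 of 10 replicates, with the tract placed on a marker-map window whose
  internal gaps stay under the detector's 100-kb limit so the experiment
  tests island calling rather than map sparsity.

These sizes keep the complete suite within a few minutes on one CPU while
leaving each property's power intact.

## Degenerate inputs and tie-breaks

* Ancestral-allele ties (exact 50/50): reference allele wins, site flagged,
  excluded from standardization bins.
* All window statistics equal: every eligible window ties at the threshold;
  all are flagged with a "degenerate distribution" warning.
* All incidences equal: same tie rule for islands; the occurrence floor
  still gates emission.
* An empirical island threshold below the occurrence floor warns that the
  floor dominates.
* Zero iHH on either allele: SNP flagged and excluded from bins rather than
  producing infinite scores.
* QC that removes every variant raises an explicit empty-panel error.

## Limitations

* EHH variants for unphased data, cross-population statistics (XP-EHH,
  XP-CLR) and composite tests are out of scope.
* The per-SNP significance convention used by some studies to count
  single-site |iHS| regions is not implemented; only the windowed
  top-quantile caller is.
* Coordinate-assembly conversion is the caller's responsibility; interval
  annotation assumes pre-harmonized coordinates.
* No consensus-ROH or F_ROH estimators; inbreeding comes from the three
  SNP-based estimators above.
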