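---
title: "Detecting and classifying Bce-like antibiotic resistance modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying Bce-like antibiotic resistance modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcescan)
```

## The biological problem

In Firmicutes, a family of antibiotic sensing/resistance units pairs a
two-component signal transduction system with an ABC transporter. The
founding example is the *Bacillus subtilis* Bce module: a response regulator
(RR, BceR), a histidine kinase (HK, BceS), a nucleotide-binding domain (NBD,
BceA) and a membrane-spanning translocator (MSD, BceB). Two architectural
features make the family recognizable from sequence alone:

* the kinase belongs to the **intramembrane-sensing** class -- exactly two
  transmembrane (TM) segments joined by a very short extracytoplasmic
  linker (3-11 residues in the *B. subtilis* kinases), with no external
  sensing domain;
* the translocator has **exactly ten TM segments** and an unusually large
  extracytoplasmic loop -- about 200 residues -- between TM7 and TM8 (the
  "O4" loop), which is functionally required for both antibiotic induction
  and resistance.

The four genes sit next to each other on the chromosome, the components
co-evolve, and the family partitions phylogenetically into six subfamilies
(subfamily VI comprising transporter-only modules with no cognate RR/HK).
`bcescan` implements the complete in-silico side of that analysis --
architecture filtering, chromosomal clustering, subfamily assignment,
co-evolution concordance and per-region conservation profiling -- together
with a synthetic-data generator that makes every stage testable offline
against a known truth.

## Pipeline and models

### Topology and the architecture filters

A `bce_topology` is an ordered segmentation of a protein into inside (`I`),
outside (`O`) and `TM` segments that tiles `[1, length]`; all external
formats (TMHMM long output, GFF3 coordinates) stay 1-based inclusive, and
the conversion to R's slicing happens only at I/O boundaries. Loops are the
residues strictly between consecutive TM segments (`inter_tm_loops()`).

The screening rules are length / exact-TM-count / one-loop windows:

| rule | length | TMs | loop measured | loop window |
|------|--------|-----|---------------|-------------|
| `hk` | 50-1000 | 2 | after TM1 | 1-20 |
| `msd` | 400-1000 | 10 | after TM7 | 100-400 |

These defaults are the windows of the original screening program; the
narrower thresholds quoted alongside the published survey counts (kinase
loop at most 12 or 14 residues; translocator loop above 170) are exposed as
the presets `results_hk12`, `results_hk14` and `results_msd170` rather than
silently substituted, because the discrepancy between the two descriptions
is real and worth preserving. `classify_architecture()` reports **every**
violated condition, not just the first, so decoys can be diagnosed; a
topology with too few TM segments for the measured loop yields the failure
`too_few_tms` rather than an error.

Loop sidedness is ignored by default (`require_outside = FALSE`): predicted
side labels flip with the N-terminus orientation, and the screening windows
are defined by loop position and length only. The full inter-TM span is
measured, not only its outside-labelled part.

### The hydropathy fallback

When no TMHMM output is available, `predict_topology_kd()` provides a
deliberately simple stand-in: Kyte-Doolittle window means (window 19,
cutoff 1.6), maximal candidate runs kept as TM segments, sides alternating
from an N-in convention. The minimum run length defaults to 9 -- half a
window -- because window overhang dilutes the mean at helix ends: a
canonical 20-residue helix flanked by hydrophilic loops produces a candidate
run of only 11-13 positions, so demanding much longer runs would reject
real-sized helices outright. The fallback is adequate for clean synthetic
material and for triage; diverged real sequences should be run through a
proper topology predictor, and the pipeline warns prominently whenever the
fallback is used.

### Component calling

Each protein is aligned locally (Smith-Waterman, BLOSUM62, affine gaps;
a gap of length $L$ costs $11 + (L-1)$) against one seed per component, and
the score is normalized by the seed's self-score so a seed scores exactly 1
against itself. The default acceptance threshold of 0.2 on that normalized
score is a declared, configurable parameter: no E-value is meaningful
without a database size, while the normalized score is deterministic and
substitution-matrix-consistent. Pre-computed BLAST tabular evidence can be
imported instead (`import_blast_tab()`, filtered by percent identity and
subject coverage, best bitscore per query). Ties between components are
broken in the fixed order RR < HK < NBD < MSD.

The four *B. subtilis* seed proteins themselves cannot be redistributed
with the package, so `synthetic_seeds()` ships a deterministic synthetic
seed set with the published seed lengths (231, 334, 253, 646 residues) and
rule-conformant topologies; real seeds can be supplied as a tagged FASTA
(`read_seeds()`).

### Chromosomal clustering

`build_clusters()` groups component-called genes per contig: consecutive
component genes separated by at most `max_gap` intervening non-component
genes (default 3) join one cluster. The survey never states its
intervening-gene tolerance; the published cluster diagrams show small
non-module gene counts, so 3 is an explicit, configurable assumption echoed
into every report header. Strand is recorded but never splits a cluster --
the modules are defined by physical proximity, not co-orientation.
Composition classes follow the survey's categories: `complete` (at least
one copy of each component), `transporter_only` (NBD/MSD only, nothing
regulatory within the scan window), `foreign_regulator` (NBD/MSD next to a
product-annotated but non-homologous regulator pair, the salXY situation),
and `partial`. Pseudogene-flagged members count toward composition but are
tallied separately.

In the full scan (`scan_modules()`), an HK call must pass the kinase rule
and an MSD call the translocator rule, otherwise the call is demoted to
`none` before clustering; RR and NBD have no architecture gate because no
topology constraint is defined for them -- their Bce-like status rests on
homology and, downstream, on tree placement.

### Subfamily assignment and co-evolution

Trees are imported (newick; node labels read as supports, values above 1
treated as bootstrap percentages and divided by 100) -- the package does
not re-run ML or Bayesian inference. All clade queries use **unrooted
bipartition semantics**: imported trees carry arbitrary rootings that must
not be trusted. `assign_subfamily()` finds the smallest edge-bipartition
side containing the query, at least one reference leaf and support at or
above `min_support`; a side whose references span more than one subfamily
leaves the query `unclassified`. The default `min_support` of 0.5 matches
the weakest clade support the published classification accepts (subfamily
V, posterior probability 0.50). The shipped reference map contains only
accessions named in the survey text (subfamilies II, IV and V) and is meant
to be extended from the figures by the user.

Co-evolution is quantified two ways: Robinson-Foulds distance between
component trees pruned to shared leaves (`rf_distance()`), and per-cluster
subfamily concordance (`concordance()`): a cluster agrees when all its
classified components name the same subfamily, and the global agreement
fraction is taken over clusters with at least two classified components.
`nj_tree()` (classical neighbor joining over Poisson-corrected local
alignment distances) is a fallback builder only.

### Conservation profiling

`partition_regions()` maps every alignment column in which the reference is
non-gapped to the reference's topology segment, labelling segments per kind
in N-to-C order (a ten-TM translocator gives I1-I6, O1-O5, TM1-TM10).
Columns where the reference is gapped belong to no region, so region sizes
are reference-defined; columns where the *other* sequence is gapped count
as mismatches. This reference-anchored reading is documented here because
the original description does not specify gap handling. Identity is raw
fractional identity per region; because the original figure's axis is
labelled as an evolutionary distance while the text speaks of mean
identity, a Poisson-corrected distance column ($-\ln(\mathrm{identity})$)
is emitted alongside rather than choosing one reading silently. The
whole-protein identity equals the region-size-weighted mean of the region
identities exactly -- a useful arithmetic invariant the tests exercise.

## The synthetic-data generator

`plant_genome()` emits genomes as ordered gene lists with a hydrophilic
background, planted complete modules (component sequences diverged from the
synthetic seeds, topologies satisfying the default rules), and decoy units
each violating exactly one screening rule: a six-TM kinase
(`wrong_tm_count`), a translocator O4 loop of 99 residues
(`loop_too_short`), an 850-residue translocator with a 401-residue loop
(`loop_too_long`), a module lacking its translocator (`missing_component`),
and a module split by a gap wider than the clustering tolerance
(`shuffled_order`). Everything is deterministic under the configuration
seed, down to byte-identical output files.

Defaults were chosen once as the simulated study conditions: 20% site
divergence from the seeds (well within homolog recovery range and far above
background similarity), up to 2 background genes planted between module
members (inside the default clustering tolerance of 3), and decoy loop
lengths of 99/401 residues sitting one residue outside the 100-400 window
so the filter is probed exactly at its boundaries.

`evolve_family()` evolves a protein family along a tree with per-site
rates. On a branch of length $b$ a site with rate $r$ is substituted with
probability $1 - e^{-rb}$, and the replacement is drawn **uniformly from
all 20 residues** -- a Jukes-Cantor-style model on 20 states under which
the expected identity between two leaves joined by path length $d$ is
exactly $e^{-rd} + (1 - e^{-rd})/20$. Drawing only *different* residues
would break that closed form (identity
$e^{-2rb} + (1-e^{-rb})^2/19$ for a two-leaf tree), so the resample-over-20
convention is the package's substitution model; it keeps the validation
closed-form exact. Indels are off, so the true alignment is the leaf
sequences themselves; the substitution model is deliberately uniform rather
than empirical because the tests need controllable identity levels, not
realism.

`plant_reference_trees()` builds per-component trees with monophyletic
reference clades for the six subfamilies (five for RR/HK, which have no
transporter-only subfamily VI) and query leaves attached inside known
clades, with configurable support downgrades to exercise the unclassified
path.

What passing these synthetic tests does **not** show: recovery of the
published genome-survey counts (those depend on a 2009 genome snapshot),
robustness of the hydropathy fallback on diverged real sequences, or
behaviour under alignment error and indels -- real alignments are imported,
not simulated.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_genomes = 2, n_modules = 2,
                  decoys = c(wrong_tm_count = 1, loop_too_short = 1),
                  n_background = 10)
sim <- plant_genome(cfg)
scan <- scan_modules(sim$proteome, sim$features, sim$topologies,
                     seeds = sim$seeds)
scan
score_against_truth(scan, sim)
```

On this configuration the scan calls the planted components, demotes the
two decoys for exactly their planted reason (`tm_count_mismatch`,
`loop_out_of_range`), and recovers both planted modules with precision and
recall 1.

## Numerical choices and limitations

* **Problem sizes.** The shipped validation uses 1,000 random topologies
  for the filter oracle, 20 genomes / 50 modules / 200 decoys for
  end-to-end recovery, 60 planted queries for subfamily recovery, 100
  replicates for the conservation-rate ordering, 100 additive matrices for
  the NJ check and 10,000 sites for the closed-form identity check.
* **Determinism.** All generators draw from an explicitly seeded RNG and
  restore the caller's RNG state; identical configurations give
  bit-identical files. Component calling, filtering and clustering are
  deterministic; ties are broken by fixed component order or lexicographic
  rules.
* **Degenerate inputs.** Empty proteomes produce empty reports with exit
  status 0; singleton clusters are allowed; a region with no columns is
  reported as missing rather than 0; trees with fewer than four shared
  leaves are a hard error for RF distance.
* **Limitations.** The package does not infer trees (beyond the NJ
  fallback), align sequences, predict signal peptides, reproduce the
  TMHMM HMM, or model the mechanistic antibiotic-sensing biology; pseudogene
  status is carried as a flag, not curated.
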