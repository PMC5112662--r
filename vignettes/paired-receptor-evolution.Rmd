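---
title: "Methods: molecular evolution of paired immune receptor gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular evolution of paired immune receptor gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceacamr)
```

# The biological problem

Paired immune receptors are gene pairs whose products share a nearly
identical extracellular ligand-binding domain but signal in opposite
directions: the inhibitory member carries ITIM/ITSM motifs in its
cytoplasmic tail, the activating member ITAM or ITAM-like motifs.
Pathogens that bind the inhibitory receptor suppress the immune
response; the activating member acts as a decoy, converting the same
binding event into a destructive signal. The amphibian *ceacam*
families (immunoglobulin-superfamily receptors on *Xenopus*
chromosome 7) are a model case: tandem clusters of tens of paralogs in
two ancient subgroups, with paired receptors in each, shaped by three
signatures this package quantifies:

1. **Diversifying selection** on the ligand-binding (IgV-like, "N")
   domain, measured as dN/dS > 1, concentrated in the CC'C''FG
   β-strand face where pathogen adhesins dock.
2. **Gene conversion** between the inhibitory and activating partner,
   restricted to the N-domain exon, which re-homogenises the decoy's
   binding surface; it shows up as long runs of codons without
   synonymous substitutions inside an otherwise diverged alignment.
3. **Asymmetric decay of homeologous loci** after
   allotetraploidization: once one partner of a pair is lost, the rest
   of the cluster degrades rapidly.

# Substitution statistics

## Site and difference counting

`count_sites()` and `count_differences()` implement pathway-averaged
counting in the Nei–Gojobori (1986) convention. For each codon
position the synonymous fraction among the non-stop single-base
changes is that position's synonymous site contribution; S + N = 3 for
every sense codon. Differences between codons are averaged over all
orderings of the differing positions; orderings that pass through a
stop codon are excluded, and in the degenerate case where every
ordering does, all orderings are used with stop-touching steps counted
as nonsynonymous. Pathways are equally weighted. Both operations are
backed by lookup tables built once per session from the standard
genetic code (no alternative codes are supported), and the test suite
checks every one of the 61 site counts and 61×61 pair counts against a
separately written enumeration oracle.

## Rates and profiles

`pairwise_dnds()` averages site totals over the two sequences, sums
differences, and corrects the proportions with the Jukes–Cantor
transform −(3/4)·ln(1 − 4p/3). A proportion at or beyond 3/4 yields a
flagged `NA` ("saturated") rather than an error, and dS = 0 yields an
*undefined* ratio rather than infinity; downstream ranking places
undefined ratios last. `cumulative_profile()` returns the running
per-codon sums of synonymous and nonsynonymous differences whose flat
synonymous stretches are the visual signature of gene conversion.

Alignments are prepared by `edit_alignment()` (drop every codon column
containing a gap or ambiguity in either sequence — the automated
counterpart of manual gap editing) or, for unequal-length inputs,
`align_codons_by_protein()`, which aligns the translations and
back-maps the gaps in 3-nt steps before editing.

One estimator property worth knowing: with strongly site-heterogeneous
ω and large divergence (dS ≳ 0.7), the whole-exon dN/dS
underestimates the rate-weighted mean ω, because nonsynonymous changes
concentrated in a few fast codons saturate before the correction can
recover them. On the simulator's inhibitory profile (44 of 107 codons
at ω = 2, rest at 0.2, dS ≈ 0.72) the expected whole-exon estimate is
about 0.66 rather than the naive 0.94. Ranking between gene classes is
unaffected — which is what the analysis relies on — and at moderate
divergence (dS ≈ 0.3) the estimate is within 20 % of the rate-weighted
expectation. Maximum-likelihood codon models that would remove this
bias are deliberately out of scope.

# Gene-conversion detection

The field traditionally reads conversion off the cumulative plots by
eye. `detect_conversion_tracts()` formalises the criterion: a
candidate tract is a maximal run of codons with zero synonymous
differences, at least `min_len` codons long (default 15). Significance
comes from a permutation null: codon columns are shuffled (seeded),
and the p-value is the add-one fraction of permutations whose longest
zero-synonymous run is at least as long as the observed run, so p ∈
(0, 1]. Defaults: `reps = 999`, α = 0.05. Alignments without any
synonymous difference are reported as *not assessable* — a recently
converted full exon has no internal contrast left, and the evidence
then comes from the exon/intron identity contrast instead
(`percent_identity_windows()`, default window 100 nt, step 25 nt,
windows with under 50 % comparable columns flagged). Multiple
non-overlapping tracts within one pair are each reported without
multiple-testing correction (flagged as such); across pairs the
pipeline applies Benjamini–Hochberg at report level.
`check_exon_restriction()` tests the hallmark of exon-limited
conversion — both tract limits within a slack (default 10 nt) of the
exon limits extended by the 2-nt splice dinucleotides.

Calibration measured by the acceptance script under the package's
default simulation conditions (150-codon exons, background dS 0.4,
40-codon tracts): recall 1.00 on 100 replicates, false-call rate 0.035
on 200 tract-free replicates at α = 0.05.

`region_contrast()` compares the per-codon nonsynonymous density
inside a named set of codon intervals (the CC'C''FG strand windows;
coordinates are user input, since 3-D modeling is out of scope)
against the remainder, with a one-sided permutation p-value. Power
measured at the default conditions (25-codon ω = 2 window vs ω = 0.2
background, dS 0.3): 1.00 over 100 replicates.

# Annotation rules

* **Motifs** (`scan_motifs()`): ITIM = `[ILVS]xYxx[ILV]`, ITSM =
  `TxYxx[VI]`, ITAM = `Yxx[LI]x{6,12}Yxx[LI]`, ITAM-like = two
  `Yxx[ILV]` modules spaced 3–5 or 13–20, or a lone module in an
  ITIM-free tail. These consensi are a design decision (the source
  analyses deferred to a web pattern server); they are arguments, not
  constants. Precedence per overlapping site: ITAM > ITAM-like >
  ITIM/ITSM; ITIM and ITSM co-report where both match.
  `classify_signaling()` maps motif content to
  inhibitory/activating/ambiguous/none; ambiguous genes are excluded
  from pairing and listed separately.
* **Pseudogenes** (`call_pseudogene()`): in-frame stop inside an N
  exon, or a non-GT donor / non-AG acceptor on an intron flanking an N
  exon, evaluated strand-aware; GC donors acceptable behind a flag
  (off by default).
* **Gene counting**: `cluster_n_exons()` single-links N-exon
  sequences at ≤ 1 % divergence (1 − identity over non-gap columns of
  a global alignment, match +1, mismatch −1, gap open −5, extend −1 —
  the metric is a design decision, the threshold is the field's rule);
  `merge_exons_to_genes()` collapses consecutive N exons with no
  non-N exon between them into one gene.
* **Orientation** (`orientation_pairs()`): all inhibitory×activating
  pairs on opposite strands within a subgroup, ordered by genomic
  distance. Distance is reported but never filtered on.

# Distance-based orthology

Protein distances are p-distances (or Poisson-corrected,
−ln(1 − p)) over non-gap columns of global BLOSUM62 alignments, or of
a mafft multiple alignment for sets (`align_proteins()`; mafft is the
one external tool the package shells out to — a deliberate trade of a
bespoke progressive aligner for a standard, deterministic one).
`build_nj_tree()` is a from-scratch neighbor-joining with two pinned
behaviours: negative branch lengths are clamped to zero with the
deficit moved to the sister branch, and Q-criterion ties break
deterministically by label order. It is validated against additive
matrices (exact recovery), the reference implementation in ape, and an
exhaustive least-squares search over all 15 five-taxon topologies.
`bootstrap_support()` resamples alignment columns and reports the
percentage of replicate NJ trees containing each bipartition.
`assign_subgroups()` cuts the NJ tree at its longest internal edge (or
2-medoid partitioning, configurable) and flags near-identical sets
(max distance < 0.1) as unsplittable.

`call_orthologs()` is input-agnostic reciprocal-best-hit logic:
orthologs across species, homeologs across L/S tags within an
allotetraploid, paralog groups as within-species mutual nearest
neighbours closer than any cross-species sequence; ties break by label
order and are flagged. The *pipeline* feeds it full-CDS nucleotide
identity rather than N-domain protein identity, for two reasons: a
converted N exon is a verbatim copy of the donor's and cannot identify
the acceptor's own lineage, and rapidly diversifying (ω > 1) N domains
are too noisy at deep separations for exact reciprocity. Using every
exon keeps the relation calls on the slowly evolving majority of the
gene.

# The simulator

`simulate_family()` generates the full statistical structure the
analysis assumes, with truth tables for every event. The default
scenario (`xenopus_like_config()`):

| parameter | value | why |
|---|---|---|
| subgroup sizes | 20 + 18 genes | observed cluster sizes |
| duplications | 118–90 time units ago | tandem expansion predating speciation |
| speciation | 60 | the two frog lineages split ~60 Mya |
| allotetraploidization | 40 | hybrid origin of the second species ~40 Mya |
| mutation rate μ | 0.006 syn subs/site/unit | ortholog N-exon dS ≈ 0.72, steady-accumulation regime |
| ω background / selected | 0.2 / 2.0 | purifying baseline; diversifying windows |
| selected windows | 44 of 107 N-exon codons | CC'C''FG-strand-like placement, inhibitory genes only |
| intron rate multiplier | 1.5 | introns visibly less conserved than exons |
| conversions | full N exon, t = 2 | recent, exon-restricted, donor = inhibitory member |
| S-locus losses | 34 of 38 at t = 35 | "> 80 % lost", no complete pair survives |

Coding sequence evolves by a proposal/acceptance single-nucleotide
process: proposals uniform over all single-base changes (a
transition-weight κ is exposed, default 1), synonymous changes
accepted at relative rate 1, nonsynonymous at the codon's ω, stop
codons rejected. The proposal count is calibrated so the expected
number of accepted synonymous substitutions per synonymous site equals
the branch length; the calibration uses the branch's starting
composition (a stationarity approximation that the neutral-calibration
check bounds: mean estimated dN/dS over 50 replicates at ω = 1 is
within 0.01 of 1). Intron and intergenic DNA evolve neutrally by exact
Jukes–Cantor sampling; the 2-nt splice dinucleotides are held fixed so
that splice-site lesions occur only where programmed. Cytoplasmic
exons evolve at ω = 0 — tails are strongly conserved — which keeps the
programmed ITIM/ITAM peptide cassettes (embedded in tyrosine-free
scaffolds) stable, so the signaling class of every simulated gene is
exactly its programmed truth.

What the simulator does *not* emulate: indels inside exons,
recombination hotspots, population-level (coalescent) variation,
transposable elements, and base-composition bias. Passing tests
therefore demonstrate correctness of the statistical machinery on
data satisfying its assumptions, not robustness to the full messiness
of genomic data; on real input the gap-editing and protein-guided
alignment steps absorb small indels, but heavily fragmented assemblies
are out of scope.

Determinism: all randomness flows from the configuration seed through
a local RNG scope, and two runs with the same seed emit byte-identical
FASTA/GFF3/truth files.

# Pipeline and reporting

`run_pipeline()` executes annotate → subgroup split → orthologs →
dN/dS → conversion scan → paired receptors → homeologous-locus
comparison, with stage toggles whose dependencies are checked up
front, a fixed seed for every permutation test, and a checksum-keyed
cache so rerunning against an unchanged input directory returns the
cached report. Thresholds actually applied (identity 80 %, tract
min_len 15, α 0.05, reps) are carried in the report. The
paired-receptor identity threshold defaults to 80 %, the lower edge of
the empirically observed 80–93 % range for such pairs. dN/dS is
skipped (with a logged warning) for pairs involving a called
pseudogene, whose N exons contain stops.

Problem sizes used by the shipped checks — 10,000-codon neutral pairs
(50 replicates), 150-codon exons for conversion/contrast calibration
(100–200 replicates), the full 38-gene two-species scenario for the
end-to-end run, and a 9-gene variant for replicated ranking — were
chosen so each check constrains its statistic well while the whole
suite stays comfortably interactive.

# Known limitations

* NG86 counting only; no transition/transversion-weighted sites, no
  ambiguity-aware counting, no ML codon models.
* The conversion detector formalises a visual criterion; it is not a
  GENECONV-style fragment test and has no power when the whole
  alignment is converted (reported *not assessable* by design).
* ITAM-like is not a standardised consensus; the default pattern is a
  configurable stand-in.
* Subgroup assignment assumes exactly two deep clades; more structured
  families need the tree, not the 2-cut.
* The published-value comparison requires the article's supplementary
  N-exon sequences, which are not redistributable here; the test that
  consumes them documents where to place the file.
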