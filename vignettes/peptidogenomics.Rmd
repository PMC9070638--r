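---
title: "Peptidogenomic discovery of non-conventional peptides with ncpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptidogenomic discovery of non-conventional peptides with ncpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpep)
```

## The method

Mass-spectrometry peptidomics identifies short endogenous peptides, but a
search against an annotated proteome can only ever return peptides from
annotated coding sequences. Peptidogenomics removes that ceiling by
searching against a database derived from the genome itself: every
chromosome is translated in all six reading frames, each frame is split at
stop codons, and every maximal stop-to-stop amino-acid segment becomes a
database record whose exact genomic interval is kept alongside the
sequence. A peptide identified from such a database can then be placed
back onto the genome and asked *where it came from*: an annotated CDS read
in its own frame (a conventional peptide, CP), or anywhere else — an
intergenic region, an intron, a UTR, the near-upstream or near-downstream
neighborhood of a gene, or a CDS read out of frame or antisense (a
non-conventional peptide, NCP).

`ncpep` implements this pipeline end to end: database construction,
peptide-to-genome mapping, CP/NCP origin classification, genome-wide
distribution statistics, overlap with external interval tracks (QTLs, LTR
retrotransposons, domestication sweeps, lncRNA loci, long-read
alignments), and a matched-random-background enrichment test of peptide
loci inside SNP-flanking windows. A synthetic-data generator plants
peptides of known origin into simulated genomes so that every stage is
testable without any external download.

## Coordinates

All coordinates inside the package are **0-based half-open** `[start,
end)`. Conversion happens only at file boundaries: GFF3 and the labeled
TSV dialect are 1-based inclusive and are converted on read/write; BED is
already 0-based half-open. A single internal convention eliminates
off-by-one drift between modules; the tests exercise the conversions at
every boundary.

## The six-frame database

`translate_frame()` translates one frame with the standard genetic code;
minus frames translate the reverse complement, frame `-1` starting at the
first base of the reverse complement, `-2` and `-3` at offsets 1 and 2. A
trailing partial codon is dropped. Any codon containing a base outside
A/C/G/T is translated as `X` — ambiguity is never resolved, even for codon
families like `GCN` whose product would be unambiguous, because a masked
or ambiguous base is not evidence of any particular residue.

`segment_frame()` splits the translation at `*`. Two rules matter:

* **`X` does not terminate a segment** — ambiguity is not evidence of a
  stop codon.
* **Leading and trailing stop-less pieces are kept** and flagged
  (`leading`, `trailing`). The construction splits purely at observed
  stops; discarding frame ends would silently lose genuine loci at
  chromosome boundaries.

With frame offset `k` and a piece spanning residues `[a, b)`, a plus-frame
segment occupies genomic `[k + 3a, k + 3b)`; a minus-frame segment over
the reverse complement of a chromosome of length `L` occupies
`[L - k - 3b, L - k - 3a)`. The whole database round-trips: re-extracting
the DNA of any segment (reverse-complemented on the minus strand) and
translating it reproduces the stored sequence exactly, which the test
suite verifies segment-by-segment on a 1-Mb two-chromosome genome with
embedded N runs, and against an independent brute-force oracle on 200
random sequences.

Segment ids are assigned deterministically in (chromosome, frame order
`+1,+2,+3,-1,-2,-3`, position) order, so two builds of the same genome are
identical. `min_len` (default 1 residue) filters short segments; the
record count of a six-frame database is sensitive to this option and to
the treatment of frame ends, so counts are only comparable between runs
that share these settings.

```{r toy}
g <- new_genome(c(c1 = "ATGAAATAGGGC"))
build_sixframe_db(g)[, c("id", "frame", "start", "end", "strand", "seq")]
```

## Locating peptides

`locate_peptides()` reports every exact occurrence of each peptide in the
segment sequences and converts each hit to a genomic interval (the hit
inherits the segment's strand and frame). Isoleucine/leucine
indistinguishability in MS is exposed as the `il_equivalent` flag,
**off** by default: enabling it changes the matching alphabet, not the
reported sequences.

Downstream genomic analyses use **single-locus peptides only**
(`single_locus_placements()`); multi-locus and unplaced peptides are
retained in the output tables but excluded from positional statistics,
because a peptide that matches several loci has no defensible single
origin.

## Origin classification

A placement is **CP** when its interval lies entirely within a CDS part
of a gene *on the same strand* and in frame with that CDS: with
phase-adjusted anchor `start + phase` (plus strand) or `end - phase`
(minus strand), the placement offset from the anchor must be 0 mod 3.
Everything else is NCP, categorized by the overlapping feature class with
the **largest overlap**, ties broken by the fixed precedence
`exonic > 5'UTR > 3'UTR > intron > upstream > downstream`:

* CDS overlap that is out of frame **or antisense** is `NCP_exonic` — in
  neither case can the peptide derive from the annotated protein.
* `upstream` is a 1-kb window anchored at the gene's TSS; `downstream`
  mirrors it at the 3' end with the same 1-kb default (only the upstream
  size is conventionally fixed; the mirror is this package's choice).
* A placement overlapping nothing, including no window, is
  `NCP_intergenic`.

Peptides straddling a CDS part boundary are `NCP_exonic` by the
containment requirement. The largest-overlap-then-precedence rule is a
deterministic, explainable resolution for multi-feature overlaps, for
which no field convention exists.

The "TSS" of a gene model is its 5' end (`start` on +, `end - 1` on -).
Annotation-level gene records do not distinguish transcription from
translation start, and distance statistics anchored to the gene 5' end
are what genome-annotation-based analyses actually compute. When a gene
has several isoforms, exons and CDS are unioned across them and
classification operates at gene level.

`start_codon()` reports the first codon of the *peptide's own* genomic
span (reverse-complemented on -). An alternative analysis would walk
upstream to the start of the containing open reading frame; we report the
peptide-anchored codon because the placement interval is the only
coordinate evidence the pipeline has, and note that the two coincide only
for peptides at their ORF start.

## Distribution statistics

* `window_density()` tiles each chromosome with non-overlapping windows
  (default 1 Mb, the conventional width for genome-scale density plots;
  step = width, so "sliding" reduces to tiling) and counts placements by
  their genomic start. On the synthetic genomes used in the tests and the
  acceptance script — hundreds of kb, not hundreds of Mb — the window is
  scaled to 50 kb so the density profile has more than a couple of cells.
* `intensive_regions()` flags windows with at least `threshold` peptides
  (default 2) and merges adjacent flagged windows. The threshold is
  deliberately a visible knob: hotspot definitions vary between studies
  and are rarely stated.
* `neighbor_distances()` and `tss_distances()` report start-to-start gaps
  and interval-to-point distances to the nearest TSS (0 when the TSS
  falls inside the placement), with summary fractions at 500 kb and 2 kb.
* `count_length_correlation()` is a Pearson correlation of
  per-chromosome counts (zero-count chromosomes included) against
  chromosome lengths; constant counts return `NA` rather than an
  artificial value.
* `stage_overlap()` produces the full Venn partition of per-sample
  peptide sets; the partition provably sums to the union size.

Peptide position for window and distance purposes is the genomic start of
the placement — a deterministic choice; at peptide scale (tens of bp) the
difference from midpoint anchoring is negligible relative to 1-Mb windows
and kb-scale cutoffs.

## Track overlap

`overlap_peptides()` assigns a peptide to every feature it overlaps by at
least `min_overlap_bp` (default 1 bp — any overlap counts, the
conventional `bedtools intersect` reading). Tracks are treated as
unstranded; QTL and sweep intervals carry no strand, and no strand rule
is imposed on lncRNA or read-alignment tracks either. A peptide may count
under several labels but once per label.

## SNP-flank enrichment

`snp_flanks()` builds `[pos - flank, pos + flank + 1)` windows (10-kb
flank default, i.e. a 20-kb region around each SNP), clips them to the
chromosome, and **merges** overlapping windows so a peptide near two SNPs
counts once. `matched_background()` draws `n_replicates` (default 100)
random fragment sets that preserve the real placements' per-chromosome
counts and per-chromosome length multisets, with uniform starts;
fragments may overlap each other — the simplest faithful null. The test
statistic is the number of placements overlapping the merged flank set;
`enrichment_test()` compares the observed count to the normal
distribution fitted to the replicate counts with an upper-tail test, and
*always* reports the empirical tail probability
`(1 + #{replicates >= observed}) / (n_replicates + 1)` alongside, since a
normal fit to 100 replicates is rough. When the replicate counts are
constant the normal p-value degenerates (1 if the observation does not
exceed the mean, essentially 0 otherwise) and a `degenerate` flag is set.

The test suite checks calibration and power at sizes chosen to make the
overlap counts well spread: a 7.5-Mb three-chromosome genome, 60 SNPs
(merged flank coverage about 15%), 500 uniform placements per null
dataset over 200 datasets, and 200 placements with a 30% planted
association over 50 datasets.

## The synthetic-data generator

`simulation_spec()` fixes the study conditions; `simulate_dataset()`
produces a genome, annotation, SNPs, planted peptides, a PEAKS-style
identification table, and feature tracks, together with a truth table.

What it emulates, and the defaults:

* a three-chromosome genome (300/220/160 kb) with i.i.d. bases at GC
  0.35, the GC range of grape-like plant genomes;
* about 60 genes per Mb, each with a 5'UTR, 1–3 CDS exons with introns,
  and a 3'UTR; the genome is rewritten at CDS sites so every coding
  sequence is ATG…stop with no internal stop;
* planted peptides dominated by intergenic origins (150 of 194 by
  default), echoing the origin spectrum reported for plant NCP surveys,
  with lengths from a discretized log-normal with median about 10.5
  residues (range 7–30);
* three developmental-stage samples (`EL32`, `EL34`, `EL36`) with
  per-sample Bernoulli detection probability 0.35, which reproduces the
  developmental-specificity pattern of small pairwise overlaps;
* 8 trait-associated SNPs (few enough that 20-kb merged flanks stay a
  minor fraction of the desk-scale genome) and a planted association
  fraction `rho` (default 0) that forces that share of intergenic plants
  into SNP flanks;
* decoy peptides verified absent from the genome by literal six-frame
  search, and observed masses with Gaussian noise (sd 0.01 Da).

Plant sites are sampled inside regions of the requested category *minus
every other feature class*, so planted classifications are unambiguous;
the local genome is rewritten to encode the peptide in the chosen frame
(genome editing guarantees the requested category counts at small genome
sizes, where rejection sampling of whole genomes would be hopeless).
After editing, every planted sequence is verified to occur exactly once
in the six-frame translation of the edited genome, and duplicates are
redrawn — so planted peptides are single-locus by construction.

What it does **not** emulate: spectral noise, retention time, missed
cleavages, isotope patterns, modifications, FDR — detection is a plain
Bernoulli draw, and identification scores are decorative. Passing tests
on synthetic data therefore demonstrate the correctness of the genomic
logic (coordinates, classification, counting, the enrichment null), not
robustness to real MS artifacts. Real background genomes are also not
i.i.d.: repeats create multi-locus peptides at a higher rate than these
simulations show.

## Numerical choices

* Monoisotopic residue masses (and an average-mass table for the
  `use_average_mass` option) are standard values to 5 decimals; water
  18.010565 Da is added once per peptide; the proton mass in m/z is
  1.007276 Da. Group mean mass ("AMV") uses monoisotopic masses by
  default, the convention of MS search-engine exports.
* Observed masses from an identification table are carried through for
  QC, but all summaries use theoretical masses recomputed from the
  sequence, so results are reproducible without spectra.
* Degenerate paths are explicit: empty groups summarize to `NA` rows, a
  constant count vector gives `NA` correlation, sd-zero backgrounds set
  the `degenerate` flag, and empty databases write empty FASTA files.

## Problem sizes in the tests

The suite builds everything it needs in code: toy chromosomes for exact
hand-checked examples, random sequences up to 1 kb against a brute-force
oracle, a 1-Mb genome for the full round-trip check, ten planting runs of
80 peptides each for classification recovery, and the calibration/power
simulations described above. These sizes are the package's own test
design; full-genome runs simply take the same code paths with larger
inputs.

## Limitations

* Six-frame translation is genomic: spliced (exon-junction) peptides are
  not enumerable from this database.
* The database record count depends on `min_len` and on keeping frame
  ends; comparisons to other constructions must match options.
* CP calls require containment in a single CDS part; a peptide spanning
  two abutting CDS parts of a spliced gene would be conservatively called
  `NCP_exonic`.
* No FDR modeling: the identification table is taken at face value.
* The matched background preserves counts and lengths per chromosome but
  not local sequence composition; GC- or repeat-driven placement biases
  are outside the null.
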