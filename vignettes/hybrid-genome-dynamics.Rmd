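---
title: "Genome dynamics of evolved allodiploid yeast hybrids: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome dynamics of evolved allodiploid yeast hybrids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriddyn)
```

## The analysis problem

An allodiploid interspecies hybrid carries one complete chromosome set
from each of two parental yeast species.  When such a hybrid is
propagated for tens to hundreds of generations, its genome accumulates a
characteristic spectrum of changes: point mutations (SNPs and short
INDELs), whole-chromosome gains and losses, segmental copy-number
changes, loss-of-heterozygosity (LOH) recombinations in which a segment
of one subgenome is replaced by an additional copy of the homeologous
segment of the other, and partial or complete loss of the mitochondrial
genome.  `hybriddyn` implements the desk-scale analysis of this process
from short-read resequencing of single-cell isolates against a combined
two-subgenome reference:

1. **mapping** — a seed-and-extend toy mapper producing alignments,
   per-window coverage, and discordant-pair / split-read evidence;
2. **variants** — pileup SNP/INDEL calling with parent-strain
   subtraction and ORF-effect annotation;
3. **cnv_loh** — coverage segmentation into integer copy numbers and
   classification of aneuploidy, segmental events, LOH substitutions and
   mitochondrial status;
4. **recombination** — clustering of junction evidence into breakpoint
   candidates with a support-fraction filter;
5. **chimera** — local assembly at retained junctions, breakpoint
   ambiguity-interval location between the homologous ORFs, and
   reconstruction of the chimeric ORF;
6. **cohort** — generation accounting, per-division mutation
   frequencies, per-nucleotide rates and cohort tallies, including
   packaged transcriptions of the published per-isolate and
   recombination tables;
7. **assays** — flow-cytometric genome-size estimation from a ploidy
   standard curve and specific-growth-rate estimation from off-gas CO2
   profiles.

Everything is exercised against a synthetic allodiploid evolution
simulator with a replayable truth ledger, so each stage is testable
without any external data.

## The synthetic allodiploid and what it does (not) emulate

`build_reference()` generates subgenome A as random sequence with
embedded ORFs (start codon, sense codons, stop codon) and derives each
subgenome-B chromosome from its A counterpart by seeded per-base
substitutions at rate `1 - target_identity`, codon-aware inside ORFs so
no in-frame stop codons arise.  The default target identity of 0.85
matches the average homology of homeologous ORFs between the two
parental subgenomes of laboratory lager-yeast hybrids; the breakpoint
tables of such experiments span roughly 70–100% pairwise ORF homology,
and the simulator exposes the identity as a parameter across that
range rather than fixing a distribution, since the real divergence
profile along chromosomes is not modelled.

Substitution-only divergence means homeologous chromosomes share a
coordinate system.  This is a deliberate simplification: it makes the
homeology map exact, keeps every simulated chimera in frame (as
observed for real recombined ORFs), and lets the truth ledger express
LOH donor segments in reference coordinates.  Real subgenomes also
differ by insertions, deletions, translocations and transposon content;
passing the synthetic suite therefore demonstrates correctness of the
calling logic, not robustness to structurally diverged references.

Isolate genomes are produced by `inject_events()` from a
`truth_ledger()`: SNPs, anchored INDELs, tandem segmental duplications,
segmental deletions, LOH substitutions (acceptor segment replaced by
the homeologous donor segment, optionally through an in-ORF
breakpoint), whole-chromosome gain/loss, and full or partial
mitochondrial loss (a contiguous deletion of 60% of the mitochondrial
contig by default; partial loss in the field's tables is reported only
qualitatively).  Donor segments are always sliced from the unmodified
reference, so event coordinates never shift under other events.  The
reference carries one mitochondrial contig per parent but the hybrid
cell carries only one mitochondrial genome; `parent_genome()` selects
it (by default the B-side, emulating inheritance from the cryotolerant
parent).

`simulate_reads()` draws fragments uniformly with Gaussian insert sizes
(defaults 450 ± 50 bp, 150 bp paired ends, 30-fold coverage) and
applies uniform substitution errors only — no quality profiles, PCR
duplicates, or coverage bias.  Origins are recorded in read names so
mapping accuracy is measurable.

Default desk-scale genomes in the test-suite are two chromosomes of
40 and 30 kb per subgenome plus 6 kb mitochondrial contigs (~150 kb
total) at 30x — large enough that every event class spans many windows
and thousands of reads, small enough that the full suite runs in about
a minute.

## Mapping and junction evidence

The mapper indexes every reference 17-mer; at 85% identity most 17-mers
carry a diagnostic substitution, which is what separates the two
subgenomes at 150 bp read length.  Candidate loci are collected by seed
voting, scored ungapped (match +1, mismatch −2), rescued with an
affine-gap glocal alignment (gap open −4, extend −1) when needed, and
ties are broken deterministically by (contig, position).  Reads mapping
equally well to both homeologous loci are flagged and contribute half a
read to the coverage of each locus, preventing systematic subgenome
bias at high-homology loci.

A subtlety discovered during development drives the split-read logic:
at an LOH junction a read is a chimera of the two homeologous
haplotypes, and its *full-length* alignment to either locus still
matches ~85% of bases on the wrong side — good enough to look like an
acceptable mapping.  Split detection is therefore attempted whenever
the best alignment carries more than two mismatches, not only when its
score is poor.  Split prefix/suffix runs are exact-match, so the
recorded junction is the end of the identical run shared by the two
haplotypes.  Same-contig diagonal shifts of up to 40 bp are left to the
gapped aligner (short INDELs); larger shifts and inter-contig splits
become junction evidence.

## Copy number, LOH and mitochondrial status

Coverage is summarized as mean depth per 1 kb window (resolving
segmental events of ten windows and more), expressed as a ratio to the
genome-wide median window depth, and segmented by recursive binary
splitting: within a segment the residual-sum-of-squares-optimal split
point is found, and accepted when the local mean shift at that boundary
(means over the three adjacent windows on each side) exceeds 0.5
copy-ratio units and both parts span at least three windows.  The local
form of the 0.5 test matters: a global between-part mean difference
dilutes towards zero for a small interior event on a long chromosome,
whereas the local shift at a true copy-number boundary is the full copy
jump.  On noiseless piecewise-constant tracks the procedure provably
lands on true changepoints and the tests compare it to an exhaustive
changepoint oracle.

Baseline copy number is 1 per homeologous chromosome (the allodiploid
state), so whole-contig copy 2 and 0 become chromosome gain and loss, a
partial copy-0 segment a segmental deletion, partial copy-2 a
duplication, and a deletion whose homeologous corresponding interval is
duplicated is merged into one LOH substitution, conserving summed copy
number at 2.  Boundaries are reported by containing or nearest flanking
ORF ids with an `end` sentinel inside the terminal window, yielding the
field's event nomenclature (`Δ` deletion, `2x` duplication, `::`
substitution), with a parser that inverts the grammar exactly.

Mitochondrial status uses the covered fraction of the mitochondrial
contigs (windows with depth ≥ 1): below 5% is complete loss (rho-),
5–80% partial loss (rho0), above 80% present.  The two thresholds are
this package's operationalization of categories that are reported only
qualitatively in the field's tables.

## Breakpoint candidates and the support filter

Discordant pairs and split reads whose end loci co-locate within 500 bp
on both sides are clustered; the candidate position is the median split
junction when split evidence exists, otherwise the innermost mate
coordinates extrapolated by half the expected mate gap.  A candidate is
retained when at least 10% (inclusive) of the reads aligned at its
locus support it and no matching candidate exists in the parent strain.
"Reads aligned at that locus" is operationalized as alignments
overlapping a window of one read length around the junction; on clonal
30x simulations true junctions then score ~0.3–0.8 while scattered
noise stays far below 10%, and the retention decision is insensitive to
the exact window width over a wide range.  Copy-neutral (reciprocal)
translocation candidates are reported with their own class rather than
dropped — the biology makes them possible even where a given experiment
found none.

## Chimeric ORF reconstruction

Reads aligning within 3 kb of a retained junction, plus their mates
wherever they map, are assembled by a deterministic greedy
overlap-layout-consensus: reads and reverse complements are
deduplicated and sorted, and contigs grow by the longest suffix–prefix
overlap of at least 30 bp at 95% identity or better.  Perfect overlaps
are preferred over merely tolerated ones; without that rule the
extension can hop between 85%-identical haplotypes roughly once per
few kilobases, which was observed and is regression-tested.

The breakpoint ambiguity interval between the two parental ORFs is the
maximal run of identical columns of their global alignment (match +1,
mismatch −1, gap −2) around the junction, reported in each ORF's own
1-based coordinates with the correspondence `a1 <-> a2`: any crossover
inside the run yields the same chimera, so the run width is the
attainable resolution and shrinks with local homology.  A fully
identical pair yields an interval covering the entire ORF.  The
junction is located by exact extension of the orf1 prefix along the
assembled contig, validated by requiring the contig to continue past
the run with orf2 sequence (a contig that merely ends inside orf1 is
truncation, not recombination — another case found by testing).

The chimera is `orf1[1..a1] + orf2[(a2+1)..len2]`, which reproduces the
truth splice exactly on simulated junctions.  Published breakpoint
tables print the locus-2 range shifted one base 3' of this
correspondence, so the table-geometry length is
`chimera_length_closed_form(a1, len2, a2) = a1 + len2 - a2 + 1`; the
packaged table satisfies it for all ORF records except two rows
(`SeTOP1`, `ScHMLALPHA2`) that deviate by one base and are whitelisted
in `validate_fixtures()`.  Frame analysis is arithmetic (length
divisible by 3) plus a frame-0 stop-codon scan before the final codon.

## Cohort statistics

With a carry-over fraction f per sequential batch cycle the population
doubles log2(1/f) times per cycle; at f = 0.07 this is 3.84, rounded to
4 generations per cycle before multiplying — the rounded form is what
reproduces every printed generation count in the packaged table from
its cycle count.  Per-division frequencies are event counts divided by
generations; per-nucleotide rates divide further by the genome size
(24.2 Mb for the combined subgenomes) and are reported to two
significant figures.  Homology entries of `"<70"` are treated as
left-censored, ranked below every numeric value and never imputed; the
cohort median is exact as long as the median rank falls on a numeric
entry.

## Assays

The ploidy standard curve regresses fluorescence on genome size with
each standard contributing its 1n and 2n cell-cycle medians (six points
from three standards by default; a 1n-only three-point mode is
available since published protocols are ambiguous on this).  A sample's
genome size averages the inverted 1n prediction and half the inverted
2n prediction, so both predict the same quantity.  Growth rates come
from the most linear window of ln(CO2 signal): among windows of at
least five consecutive positive readings reaching R² ≥ 0.98 the longest
is taken (ties by R²), making the estimator invariant to multiplicative
signal scaling and robust at both the 0.35 h⁻¹ and 0.07 h⁻¹ regimes.
With no window reaching R² ≥ 0.98 the result is an explicit "no
exponential phase".

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout; conversion to 0-based
  half-open happens only at the SAM/BED boundary.
* All randomness flows from one integer seed through per-operation
  derived streams, so a run manifest (`run_pipeline()`) suffices to
  reproduce a run byte-for-byte.
* Point-mutation nomenclature is ASCII (`ScSFL1^T605A`,
  `SeMED2^462+3N`); copy-event nomenclature keeps the field's `Δ`.
* The pipeline interface is the exported R functions; `run_pipeline()`
  orchestrates simulate → map → call → cnv → recomb → chimera →
  summarize and writes FASTA/FASTQ/SAM/VCF/BED/TSV intermediates plus a
  manifest.

## Known limitations

* The mapper is a desk-scale substitute for a production aligner: no
  FM-index, no base-quality-aware scoring, not intended beyond ~10 Mb
  references.
* Coverage-only LOH detection (as in the motivating experiments) —
  allele-fraction evidence is not used, and subclonal events are out of
  scope.
* The assembler is greedy and suited to clonal, high-depth local data
  only.
* Synthetic subgenomes are substitution-diverged; conclusions about
  structurally diverged real references require external validation.
* Growth-rate and genome-size estimators take summary inputs (CO2
  series, fluorescence medians); raw flow-cytometry event processing is
  out of scope.
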