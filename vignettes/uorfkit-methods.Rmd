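---
title: "uorfkit: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uorfkit: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfkit)
```

This vignette is the package's own account of its methods: what is
computed, which knobs matter and why their defaults are what they are,
what the simulator does and does not emulate, and where the design was
genuinely open.

## Coordinates and annotation dialects

All internal coordinates are **1-based closed** intervals, the
IRanges/Bioconductor convention. Each external format converts exactly
once, at its reader or writer: GTF/GFF3 are natively 1-based closed;
refFlat/genePred tables, BED and bedGraph are 0-based half-open on disk.
Using a single internal convention (and paying the conversion only at the
boundary) is what prevents off-by-one drift; the choice of the R-native
convention over the 0-based one means every internal number can be handed
to IRanges, Biostrings `subseq`, or plotted against a sequence without
arithmetic.

Annotation dialects differ in whether the annotated CDS includes the stop
codon. Internally the CDS bounds *always* include the stop, so the 5′ UTR
is everything before `cds_start_tx` and a uORF stop at the pORF start can
be classified unambiguously. The reader flag `cds_includes_stop`
(default `TRUE`) normalizes input that excludes it by extending the CDS
3 nt on its 3′ side; the extension is genomic, so annotations whose stop
codon is split across an exon junction must be supplied with the stop
included (the reader errors rather than guessing).

Chromosome names match exactly; `normalize_chroms()` exists for deliberate
"chr"-prefix harmonization but is never applied implicitly, because silent
aliasing is a classic source of cross-assembly mistakes.

## uORF definition and classification

A uORF is a start codon in the 5′ UTR followed by an in-frame stop codon.
`scan_uorfs()` examines every transcript position `p < cds_start_tx`; a
position whose triplet is in `start_codons` (default ATG only — near
cognate starts CTG/GTG/TTG/ACG sit behind `report_near_cognate` for
exploration) yields at most one call, produced by walking triplets from
`p` to the **first** in-frame TAA/TAG/TGA. Classification relative to the
pORF start:

* **upstream** — the stop codon ends before the pORF start;
* **overlapping** — the stop codon ends at or after the pORF start and the
  frame differs from the pORF's;
* **n_terminal_extension** — in the pORF frame with no intervening stop.
  This is not a uORF (its "stop" is the pORF's own) and is excluded unless
  `include_n_terminal_extension = TRUE`;
* **no_stop** — no in-frame stop before the transcript end; reported with
  the stop field absent so pathological annotations surface instead of
  disappearing.

Peptide lengths count amino acids including the initiator Met and
excluding the stop: a 30-nt span (stop included) encodes 9 aa. Multiple
ATGs sharing one stop are reported individually — each is a distinct
initiation site, which is exactly the resolution at which initiation-track
evidence applies — with `collapse_same_stop` available when one row per
stop is wanted.

`ablate_start()` reproduces the standard uORF-disruption control in
silico: the ATG's first base becomes T (ATG → TTG), which removes exactly
that call on rescan while leaving calls outside the edited base untouched.

## Ribo-Seq coverage model

Coverage tracks are sparse per-genomic-base values of one kind
(footprint, initiation, mRNA); bedGraph is the primary on-disk format
because it is plain text and byte-reproducible, with fixed/variable-step
wiggle also read. Binary bigwig is deliberately not a dependency of the
I/O path: nothing in the desk-scale workflow needs a binary format, and
text keeps fixtures diffable.

**Aggregation is a per-coordinate sum** of raw values across datasets.
Summation amplifies consistent low-coverage signal (a mean would not); for
inputs that were already depth-normalized, `method = "mean"` divides the
sum by the dataset count. No further normalization or peak-calling
threshold is applied — the aggregate is evidence to be projected and
inspected, not a caller.

Projection onto a transcript is strand-aware per-base lookup; intronic
signal contributes nothing, and the projected total equals the track total
restricted to exonic bases (a conservation property the tests enforce).

Translation evidence for a uORF is three numbers plus a ratio:

* `uorf_occupancy` — mean footprint value over the uORF span (start
  through stop codon);
* `uatg_init`, `patg_init` — initiation signal summed over a window of
  ±3 nt (default) around the first base of the uORF and pORF start codons.
  The window absorbs small discrepancies in how initiation libraries
  assign a footprint to the codon; it is configurable because the right
  slop depends on the upstream processing of the tracks;
* `init_ratio = (uatg_init + ε)/(patg_init + ε)` with pseudocount
  ε = 0.5. The pseudocount keeps the ratio finite at unexpressed pORF
  starts — which is precisely the interesting case, since strong uATG
  initiation with little pATG initiation is the signature of uORF-mediated
  repression. Ratios well above 1 support an actively translated uORF.

## ASO design rules

The anchoring rule implements "5′ end complementary to the start codon"
literally: the target window is the `L` transcript bases **ending at the
last base of the start codon**, and the ASO is the window's reverse
complement. Consequences, both enforced by tests: an ATG-anchored design
always begins `CAT`, and extending the design (16mer → 18mer) adds bases
at the ASO 3′ terminus while the 5′ anchor stays fixed.

Chemistries are per-position sugar annotations (DNA, RNA, 2′OMe, MOE, LNA)
plus per-linkage backbones (PO/PS). Uniform schemes set one sugar and one
backbone throughout; gapmer schemes (`"a-b-c"`) set modified flanks around
a central DNA gap with a uniform backbone. Bases are stored in the DNA
alphabet regardless of sugar, so all complementarity arithmetic lives in
one alphabet; `render_bases()` displays U at RNA-family sugar positions.

Scrambled controls permute the bases while copying sugars and linkages
byte-for-byte, so control and on-target oligo differ only in sequence.
Beyond chemistry preservation the generator adds one constraint of this
package's own choosing: the control may not retain a contiguous
reverse-complement run of ≥ 7 nt against the original target window
(equivalently, no shared 7-mer with the on-target bases), because a
control that can still base-pair a third of the target is a poor control.
The threshold is configurable; generation is rejection sampling,
deterministic given the seed, and reports its best candidate when the
constraint is unsatisfiable.

## Oligo mass model

Masses are assembled from **elemental composition**, never per-residue
constants, so a new chemistry is one table row. The model: each position
contributes its glycosidic base (base minus one H) plus its sugar moiety
(DNA C5H9O3; RNA +O; 2′OMe +CH2O; MOE +C3H6O2; LNA +CO relative to DNA);
each internucleotide bond contributes a phosphodiester condensation
(H3PO4 − 2 H2O = {P, 2 O, −1 H}), with PS substituting one S for one
non-bridging O; termini default to 5′-OH/3′-OH (typical for synthesized
ASOs without conjugates; `five_prime = "phosphate"` adds HPO3). Reported
masses are neutral free-acid values, average or monoisotopic.

One base-identity subtlety: 2′-O-methyl RNA oligos carry uracil, whereas
MOE and LNA pyrimidines are conventionally the 5-methyl forms (i.e. T).
Since bases are stored as T throughout, `oligo_mass()` counts a stored T
as U at positions whose sugar is in `u_sugars` (default `RNA`, `2OMe`) and
as T elsewhere. The default matches the common synthesis conventions for
these chemistries and is an explicit argument for oligos that deviate.

`mass_qc()` applies the 0.2 % relative window used for oligo identity
checks by MALDI-TOF and LC-MS deconvolution: computed-vs-observed
agreement inside that window is treated as confirmation of identity.

## Quantification arithmetic

`pfaffl_ratio()` is the efficiency-corrected relative quantification
`E_t^ΔCq_t / E_r^ΔCq_r`, with ΔCq = control − treated. Efficiencies are
*inputs* (amplification factor per cycle, determined externally, e.g. by
LinRegPCR-style curve analysis); replicate Cq values are averaged on the
Cq scale before exponentiation, the standard practice. At
`E_t = E_r = 2` the expression collapses to the Livak `2^−ΔΔCq` form,
which the tests verify as an identity.

Plate normalization divides a per-well signal by a per-well normalizer
(Renilla/firefly for reporters; target band / loading band for blots) and
scales all ratios by the reference group's **arithmetic mean**, so the
reference mean is exactly 1 and every value is invariant to plate-wide
rescaling. When wells come from several independent experiments the
default is to scale within each experiment before pooling
(`scale_per_experiment = TRUE`): per-experiment scaling removes
between-experiment transfection-scale differences, which is the usual
reason each experiment carries its own control wells; pooling raw ratios
first remains available behind the flag. Missing wells are dropped with a
warning, never imputed. Group comparisons (t test, one-way ANOVA + Tukey)
are thin wrappers over `stats` — deliberately not bespoke.

## The simulator: what it emulates and what it does not

`make_genome_and_annotation()` plants uORFs whose recovery is guaranteed
at the string level, independently of the scanner: background 5′ UTR
sequence is generated with every ATG trigram destroyed (so planted starts
are the only starts), upstream uORFs are `ATG + safe codons + TAA` wholly
inside the UTR, and overlapping uORFs end their TGA on the first base of
the pORF ATG (placing them in frame 1 — the one overlap geometry whose
stop can share a base with the pORF start). "Safe" codons are drawn from
{C,G,T}³, which can contain neither stops nor parts of an ATG. The
`no_stop` class is detected by the scanner but not plantable: forcing an
absent stop would require controlling the entire 3′ remainder of the
transcript, in tension with keeping an intact pORF.

Coverage noise is Poisson per base (the natural count model), with planted
initiation spikes across the three bases of each start codon and a
footprint plateau over the uORF; quantification noise is lognormal
multiplicative (the simplest non-negative multiplicative model), with
`noise_cv = 0` giving exact recovery. Default study conditions for the
quantification fixtures are 4 replicates per group at 10 % CV with a
5.5-fold planted reporter effect — a derepression of the magnitude seen
when a repressive uORF is ablated — and these defaults are fixed, not
tuned per run.

Determinism: one global seed expands into per-component child seeds via a
fixed counter scheme (`child_seed()`), so adding a new simulated output
never shifts the random streams of existing ones, and identical spec +
seed yields byte-identical FASTA/GTF/bedGraph/TSV files.

What the simulator does **not** emulate, and hence what passing tests do
not show about real data: ribosome dynamics (no codon-level periodicity,
no P-site offsets, no reinitiation or leaky scanning), sequencing biases
(no ligation/PCR artifacts, uniform mappability), realistic UTR base
composition (background deliberately excludes ATG, real UTRs do not), and
annotation mess (one clean isoform per locus). Tests against fixtures
establish that the arithmetic is right, not that biological inference from
noisy public tracks will be.

## Numerical choices and degenerate inputs

* Window truncation: initiation windows clip at transcript ends rather
  than erroring; a position outside the transcript is an error.
* Non-exonic genomic positions map to `NA` (a sentinel), not an error —
  callers projecting tracks need the distinction routinely.
* Aggregation deduplicates coordinates by summation in the constructor, so
  track algebra is associative and commutative by construction; zero
  values are dropped to keep storage sparse.
* `translate_orf()` errors on N within a codon before the stop; Ns after
  the stop are unreachable by construction.
* Ties in `collapse_same_stop` resolve to the 5′-most start, the one the
  scanning ribosome meets first.
* Scramble rejection sampling caps at `max_tries` and reports the best
  candidate seen, so unsatisfiable constraints fail loudly with
  actionable output.

## Problem sizes used by the test suite

The property suites run at sizes chosen to exercise the invariants
thoroughly while keeping the default test run fast: 1000 randomized
transcripts for coordinate round-trips, 1000 random coding sequences for
the scanner-vs-oracle comparison, 100 randomized planting specs for
generator/scanner cross-validation, and 40–60 Monte-Carlo repetitions for
fold-recovery checks. The acceptance script uses the packaged worked
example (~1.4 kb transcript), a 6-oligo mass panel, 6 simulated
transcripts for evidence ranking, and 4-replicate quantification tables.

## Known limitations

* The packaged worked-example transcript is synthetic: it reproduces the
  uORF *architecture* of the RNASEH1 mRNA (one pORF-overlapping uORF,
  9-aa peptide), not its sequence; analyses of the real transcript should
  start from the genuine RefSeq record and annotation.
* Overlapping uORFs are planted only in frame 1 (see above); the scanner
  itself handles both frames.
* No Kozak-context scoring, thermodynamics (Tm/ΔG), or off-target search:
  design output is an anchored, chemistry-annotated sequence, not a ranked
  screen.
* Coverage inputs must already be coverage: no alignment, P-site
  offsetting, or ORF-calling statistics.
* Mass calculation is scalar neutral mass; charge-state deconvolution and
  adduct handling belong to the instrument software.
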