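# uorfkit

Upstream open reading frames (uORFs) — a start codon in a transcript's 5′
UTR followed by an in-frame stop codon — typically repress translation of
the downstream primary ORF (pORF). Blocking a uORF start codon with a
steric block antisense oligonucleotide (ASO) is a proposed route to
targeted gene *up*regulation, and testing that idea requires a chain of
desk work that this package implements end to end for any transcript:

1. **Transcript models** — build spliced transcripts from a genome FASTA
   plus GTF/GFF3/refFlat annotation, with exact genomic ↔ transcript
   coordinate maps on both strands (`read_annotation()`,
   `spliced_sequence()`, `transcript_to_genomic()`).
2. **uORF detection** — scan the 5′ UTR for start codons and walk codons to
   the first in-frame stop (TAA/TAG/TGA), classifying each call as
   *upstream* (stop before the pORF start), *overlapping* (stop at/after
   the pORF start, frame ≠ 0), *N-terminal extension* (in-frame, no
   intervening stop; not a uORF, excluded by default), or *no_stop*.
   Peptides are translated with the standard code, initiator Met included
   (`scan_uorfs()`, `translate_orf()`), and start codons can be ablated in
   silico, ATG → TTG (`ablate_start()`).
3. **Ribo-Seq evidence** — aggregate per-dataset coverage tracks
   (footprint / initiation / mRNA; bedGraph or wiggle) by per-coordinate
   sum, project them onto transcript coordinates, and score uORF
   translation: mean footprint occupancy over the uORF, windowed initiation
   peaks at the uORF ATG and the pORF ATG, and their pseudocounted ratio
   `init_ratio = (uATG + ε)/(pATG + ε)` (`aggregate_tracks()`,
   `project_track()`, `translation_evidence()`).
4. **ASO design** — anchor an antisense oligo so its 5′-terminal three
   nucleotides pair the uORF start codon (an ATG-start design always begins
   `CAT`, and an 18mer extends a 16mer at the ASO 3′ terminus), apply
   uniform chemistries (e.g. PO-2′OMe, PS-MOE) or gapmer patterns
   (3-10-3 LNA/PS, 5-10-5 MOE/PS), and generate scrambled controls that
   keep base composition and the full sugar/linkage pattern
   (`design_uorf_aso()`, `apply_chemistry()`, `scramble_control()`).
5. **Mass QC** — expected average/monoisotopic masses of modified oligos
   assembled from elemental composition (PS swaps one non-bridging O for S
   per linkage; 2′OMe/MOE/LNA modify the sugar formula), checked against an
   observed deconvoluted mass at the 0.2 % relative window used for
   MALDI-TOF / LC-MS identity checks (`oligo_mass()`, `mass_qc()`).
6. **Expression quantification** — the Pfaffl efficiency-corrected qPCR
   ratio `E_t^ΔCq_t / E_r^ΔCq_r` (reducing to the Livak `2^−ΔΔCq` at
   E = 2), dual-luciferase (Renilla/firefly) and loading-control
   normalization with the control-group mean scaled to exactly 1
   (`pfaffl_ratio()`, `dlr_normalize()`, `loading_normalize()`).
7. **Simulator** — deterministic fixtures with planted ground truth:
   genomes/annotations whose UTR background contains no stray ATG, coverage
   with planted initiation peaks, and quantification tables with planted
   fold effects (`make_genome_and_annotation()`, `make_coverage()`,
   `make_quant_tables()`, `simulate_fixture()`).

A thin command-line front end (`inst/cli/uorfkit.R`) exposes `scan`,
`design-aso`, `scramble`, `mass`, and `simulate` subcommands.

## Worked example

The package ships a small **synthetic** transcript
(`inst/extdata/synthetic_RNASEH1_like.*`, generated by the package's own
simulator) engineered to share the uORF architecture of the RNASEH1 mRNA:
one uORF overlapping the pORF start, encoding a 9-amino-acid peptide.

```r
library(uorfkit)
fa  <- system.file("extdata", "synthetic_RNASEH1_like.fa",  package = "uorfkit")
gtf <- system.file("extdata", "synthetic_RNASEH1_like.gtf", package = "uorfkit")
tx  <- spliced_sequence(read_annotation(gtf)[[1]], read_genome(fa))

(calls <- scan_uorfs(tx))
#>                transcript_id start_tx stop_tx_end    category frame_vs_porf
#> synthetic_RNASEH1_like_tx001       72         101 overlapping             1
#>   peptide peptide_len
#> MRRLLLLFS           9
```

One uORF: its ATG sits at transcript position 72, 29 nt upstream of the
pORF start (position 101 is the last base of its TGA, overlapping the pORF
ATG in frame 1), and its 30-nt span encodes 9 aa. Design the anchored ASO,
give it the phosphodiester 2′-O-methyl chemistry, and scramble a control:

```r
aso <- apply_chemistry(design_uorf_aso(tx, calls[1, ], 16),
                       uniform_chemistry("2OMe", "PO"))
render_bases(aso)                       # "CAUGUAGGCAAUCCUU" - 5' CAU pairs the AUG
oligo_mass(aso, "average")              # 5266.49 Da
render_bases(scramble_control(aso, seed = 1))  # "CGGCACUUCUAAAUUG"
```

Overlay simulated Ribo-Seq coverage with a planted initiation peak at the
uORF ATG and quantify a uORF-ablation (TTG) reporter experiment with a
planted 5.5-fold effect:

```r
cov <- make_coverage(tx, uorf = calls[1, ], seed = 1)
translation_evidence(tx, calls[1, ],
                     project_track(cov$footprint, tx),
                     project_track(cov$initiation, tx))
#> uorf_occupancy uatg_init patg_init init_ratio
#>           4.93        89         5       16.3      # strong uATG initiation

qt <- make_quant_tables(folds = c(WT = 1, TTG = 5.5), seed = 1)
summarize_ratios(dlr_normalize(qt$luciferase, "WT"))
#> group  mean    sd n
#>    WT  1.00 0.123 4      # reference mean is exactly 1
#>   TTG  5.71 1.350 4      # recovered ~5.5-fold derepression
```

`init_ratio` ≈ 16 says initiation at the upstream ATG dwarfs initiation at
the pORF ATG — the coverage signature of uORF-mediated repression — and the
TTG mutant's ~5.5-fold luciferase gain is what relieving that repression
looks like in a reporter assay.

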