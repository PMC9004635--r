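---
title: "Methods: ribogrid-based quantification of ribosome profiling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ribogrid-based quantification of ribosome profiling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribogridkit)
```

## The model

Ribosome profiling sequences the ~28 nt mRNA fragments protected by
translating ribosomes. A footprint aligned to a transcript is summarised
by two numbers: its aligned length $\ell$ and the 0-based transcript
position $p$ of its 5′ end. ribogridkit's central object, the
**ribogrid**, is the per-transcript matrix

$$ C_{\ell p} = \#\{\text{footprints of aligned length } \ell
   \text{ with 5′ end at } p\}, $$

with rows spanning a configurable length range and one column per
transcript nucleotide. The package treats this matrix as a sufficient
statistic: every downstream quantity is a function of $C$ alone, and the
test suite verifies, on simulated libraries, that frame proportions,
metagene profiles and codon densities computed from $C$ equal brute-force
recomputation from the raw alignment stream.

The ribosome's A-site — the codon being decoded — is located from a read
end by a length-specific displacement $d(\ell)$ supplied by the user
(protocols differ by organism and nuclease):

* 5′ anchor (typical for eukaryotes): $a = p + d(\ell)$
* 3′ anchor (typical for bacteria): $a = (p + \ell - 1) - d(\ell)$

$a$ denotes the **first nucleotide of the A-site codon**. This is a
convention this package fixes and documents rather than a biological
claim; any single-nucleotide convention works as long as it is applied
consistently, and the two anchors are exactly interchangeable via
$d_{3'}(\ell) = \ell - 1 - d_{5'}(\ell)$ (a tested identity). Read
lengths absent from the displacement table are excluded from A-site
analyses and tallied, never guessed.

Derived quantities:

* **Reading frame** of a position $x$ relative to the start codon at
  $s$: $(x - s) \bmod 3$ with the mathematical mod, so upstream positions
  also land in $\{0,1,2\}$. Frame 0 is the annotated frame.
* **Codon density**: codon $c$ of the CDS receives
  $\sum_{\ell, p\,:\, a(\ell,p) \in [s + 3c,\, s + 3c + 3)} C_{\ell p}$,
  with A-sites outside the CDS (UTRs or pads) excluded and tallied by
  reason. Conservation — density + exclusions = grid total — is asserted
  throughout.
* **Gene count** $c_g$: CDS-assigned A-site footprints; an ORF-level
  quantity by design, not the count of all transcript-mapped reads.
* **TPM**: with $L_g$ the CDS length in codons,
  $\mathrm{TPM}_g = 10^6 (c_g/L_g) / \sum_h (c_h/L_h)$, so the sample sums
  to $10^6$ exactly (an all-zero sample is flagged degenerate instead of
  propagating NaN).
* **Periodicity score** of a metagene profile $y$ (length a multiple of
  3; the natural $2w+1$-point window is trimmed by one point): after mean
  subtraction, the DFT magnitude at period 3 divided by the summed
  one-sided non-DC magnitudes. The score lies in $[0,1]$; a flat profile
  scores 0 by convention. This is an artifact-level summary used to make
  "the profile is 3-periodic" assertable — not a published statistic.
* **Codon–feature correlation**: each qualifying gene's codon-density
  vector is divided by its own mean over covered codons (removing
  gene-level abundance); normalised densities are averaged per codon
  identity across genes and positions and compared with a user-supplied
  per-codon feature (e.g. tRNA gene copy numbers) by Spearman rank
  correlation. Significance uses a seeded label-permutation test (1,999
  permutations by default) because 61 tied, non-normal observations make
  asymptotic formulas unattractive.

## 5′ non-templated mismatch trimming

Some viral reverse transcriptases append non-templated bases to cDNA 5′
ends. After alignment these appear as a run of $k$ mismatches anchored at
read offset 0, and they shift the apparent 5′ end by $-k$ — which
scrambles frame statistics computed from 5′ ends. `trim_5p_mismatch()`
locates the run from the MD tag and, when $k \le$ `max_trim`, removes
those bases and rewrites POS, CIGAR, MD and NM consistently; when
$k >$ `max_trim` the record is discarded to a separate stream, on the
reasoning that long terminal mismatch runs more likely indicate
mis-mapping than polymerase behaviour. `max_trim` defaults to 2, matching
the 1–2 base additions the mechanism produces; it is configurable. Only a
*consecutive* run anchored at offset 0 triggers trimming — an isolated
internal mismatch never does, because non-templated addition is strictly
terminal. Gapped 5′ termini pass through untrimmed with a warning
counter. The operation is idempotent, and on simulated libraries with
planted additions the trimmed sample's frame-0 proportion equals the
no-addition control exactly (the simulator shares molecule-level draws
between the two conditions).

## Coordinate and data conventions

All in-memory coordinates are 0-based half-open; 1-based inclusive
coordinates exist only at the GFF3/SAM/report boundaries. Transcripts are
single-exon by construction (a transcriptome FASTA is already spliced),
so minus-strand CDS annotations and minus-strand alignments are errors
and discards respectively — a footprint antisense to a transcript is not
a ribosome footprint on it. Multiple contiguous CDS lines merge; gapped
ones are an error; at most one ORF per transcript is supported. CDS
lengths not divisible by 3 exclude the transcript with a warning (frame
statistics would be undefined), upgradeable to a hard error.

The H5 schema (version 1.0) is deliberately self-describing: root
attributes `schema_version`, `sample_name`, `min_length`, `max_length`,
provenance (`source_bam`, `created`, `tool_version`) and
`transcript_order` (HDF5 iterates links in name order; the attribute
preserves build order so write→read is an exact identity); one group per
transcript with `transcript_length`, `cds_start`, `cds_end` attributes
and a chunked, gzip-compressed integer `reads` dataset. Missing
attributes and non-integer datasets are schema errors naming the
offender. Writes are byte-deterministic given a pinned `created`
timestamp, which the pipeline exposes so that identical configurations
reproduce identical bytes.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_length`, `max_length` | 10, 50 | nt | spans reported footprint sizes across archaea, bacteria and eukaryotes; rows outside carry no information |
| A-site offsets | 26–32 nt → 14–16, 5′ anchor | nt | the conventional yeast-style table (15 for the canonical 28-mer); always user-overridable, per length |
| `max_trim` | 2 | nt | 1–2 base additions are the documented mechanism; longer runs suggest mis-mapping |
| `max_mismatches` | 1 | nt | barcode Hamming budget; sheets with barcodes closer than twice the budget are rejected at construction |
| `min_reads` | 64 | reads/gene | frame and codon proportions from a handful of reads are noise; flagged, not dropped |
| `metagene_window` | 25 | codons | wide enough to show initiation context and periodicity; 5′-end counting by default because the length-dependent offset is the diagnostic of interest |

Demultiplexing ties (two barcodes at the same minimal qualifying
distance) go to `Unassigned` rather than first-wins: deterministic and
conservative, since mis-assignment is worse than loss.

## The simulator and what passing tests mean

`simulation_spec()` defines a padded-ORFeome experiment: transcripts are
`pad + ATG + random sense codons + stop + pad` (default 50 nt pads, CDS
80–250 codons), gene abundances are log-normal (sdlog 1), and each
molecule gets an A-site codon (uniform or dwell-weighted by codon
identity), a frame offset from the planted frame weights (default
0.85/0.10/0.05), and a read length from the planted length distribution
(default dominated by 28-mers). The 5′ position is then *derived by
inverting the planted offset table*, so the generative process is the
exact inverse of the analysis. Optional layers: UMIs, PCR duplication
(`1 + Poisson`), sample barcodes with planted 0/1/2-mismatch corruption,
and 5′ non-templated additions sampled to always mismatch the reference.
Alignments are emitted as if perfectly aligned, with internally
consistent CIGAR/MD/NM — the package never depends on an external
aligner.

All randomness flows from one seed (`seed` for the transcriptome,
`seed + 1` for the library), and molecule-level draws precede
addition-level draws so that two runs differing only in the addition
probability share identical molecules — this turns the trimming
comparison into an exact identity rather than a statistical one.

What the simulator does *not* model: sequencing errors inside the
fragment, quality-score structure, rRNA contamination, biased fragment
ends, or alignment ambiguity. Passing tests therefore demonstrate that
the implementation is exact and self-consistent under the stated
generative model, not that any particular biological dataset will show
these properties.

Scales used in the shipped checks (chosen as comfortable desk-scale
sizes that still give tight binomial/multinomial bounds): end-to-end
conservation at 2,000 transcripts × 100,000 footprints; statistical
recovery at ~2,000 reads per gene with 3-standard-error bounds;
dwell-signal recovery at 100,000 reads over 30 genes against a 61-codon
feature table; periodicity on 20 paired seeded replicates.

## Numerical and degenerate-input choices

* Proportions are exact ratios of integer counts; no smoothing.
* `periodicity_score` defines 0/0 as 0 (flat profile).
* Degenerate TPM (all-zero) and degenerate correlation (constant feature
  or density) return flags instead of NaN.
* Tie-break in barcode assignment is "no assignment", never order-based.
* Empty inputs (no reads, zero-depth simulation, empty annotation) yield
  empty but well-formed outputs everywhere; this is tested.

## Known limitations

* Only ungapped transcriptome alignments are trimmed; spliced/genomic
  BAM is out of scope by design.
* UMI deduplication is exact-match only; network-based near-miss
  collapsing is delegated to dedicated external tools via the identifier
  convention.
* One CDS per transcript; extra ORFs are reported, not analysed.
* Alignment itself is external: the pipeline consumes
  transcriptome-aligned BAM and stops with a clear message when given
  FASTQ only.
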