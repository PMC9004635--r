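# Example ribogridkit run configuration.
# Only fasta, gff3 and one sample are required; everything else below is
# shown with its default value.

fasta: transcriptome.fasta        # transcript sequences
gff3: transcriptome.gff3          # CDS positions within the transcripts

samples:                          # name -> transcriptome-aligned BAM
  wildtype_1: wildtype_1.bam

output_dir: ribogridkit_out

# --- A-site assignment ----------------------------------------------------
# offsets: offsets.tsv            # TSV (read_length, offset); omit to use
                                  # the shipped eukaryote-style table
asite_anchor: five_prime          # or three_prime (e.g. bacteria)

# --- optional pre-alignment stages (FASTQ input) ---------------------------
demultiplex: false
# barcode_sheet: barcodes.tsv     # headerless TSV: sample <TAB> barcode
max_mismatches: 1                 # Hamming budget per barcode
extract_umi: false
umi5_length: 0                    # UMI nt at the read 5' end
umi3_length: 0                    # UMI nt at the read 3' end
dedup: false                      # exact-match UMI deduplication

# --- alignment post-processing --------------------------------------------
trim_5p: true                     # trim non-templated 5' mismatches
max_trim: 2                       # longer mismatch runs are discarded
min_length: 10                    # aligned-length bounds of the ribogrid
max_length: 50

# --- summaries -------------------------------------------------------------
min_reads: 64                     # coverage floor for frame/codon statistics
metagene_window: 25               # metagene half-window, codons
frame_from: asite                 # or five_prime (raw 5'-end diagnostics)
# trna_table: trna_copies.tsv     # per-codon feature (codon <TAB> value)

seed: 1
timestamp: "1970-01-01T00:00:00Z" # pinned for byte-reproducible outputs
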