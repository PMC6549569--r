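# Small in-code fixtures shared across test files.

make_sheet <- function() {
  data.frame(sample = c("A", "B"),
             index1 = c("ACGTACGT", "TTTTCCCC"),
             index2 = c("GGGGAAAA", "CATGCATG"),
             stringsAsFactors = FALSE)
}

# One read-quartet row with index reads built from fixed index + UMI.
make_quartet <- function(name, i1_fixed, i2_fixed, umi1 = "AACCGT",
                         umi2 = "TTGGCA", seq = "ACGTACGTAC") {
  data.frame(name = name,
             read1_seq = seq, read1_qual = strrep("I", nchar(seq)),
             read2_seq = seq, read2_qual = strrep("I", nchar(seq)),
             index1_seq = paste0(i1_fixed, umi1),
             index2_seq = paste0(i2_fixed, umi2),
             stringsAsFactors = FALSE)
}

# Tagged aligned record rows for consensus tests: one molecule family with
# `n` read pairs; both mates carry `seq` aligned at [start, start+len).
make_family_records <- function(n, seqs_m1, seqs_m2 = seqs_m1,
                                chrom = "chr1", frag_start = 100L,
                                frag_end = NULL, umi1 = "AAAAAA",
                                umi2 = "CCCCCC", sample_id = "A",
                                orientation = "F1R2", qprefix = "r") {
  len <- nchar(seqs_m1[1])
  if (is.null(frag_end)) frag_end <- frag_start + len
  m2_start <- frag_end - nchar(seqs_m2[1])
  data.frame(
    qname = rep(paste0(qprefix, seq_len(n)), 2),
    sample_id = sample_id, chrom = chrom,
    frag_start = frag_start, frag_end = frag_end,
    orientation = orientation, umi1 = umi1, umi2 = umi2,
    mate = rep(1:2, each = n),
    start = c(rep(frag_start, n), rep(m2_start, n)),
    end = c(rep(frag_start + len, n), rep(frag_end, n)),
    seq = c(seqs_m1, seqs_m2),
    stringsAsFactors = FALSE)
}

# Minimal pileup row(s).
make_pileup <- function(pos = 500L, depth = 1000L, alt_count = 0L,
                        other_count = 0L, n_count = 0L, ref = "A",
                        alt = "T", chrom = "chrS") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             depth = depth, alt_count = alt_count,
             other_count = other_count, n_count = n_count,
             stringsAsFactors = FALSE)
}
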