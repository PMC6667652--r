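# Small in-code fixture builders shared across test files.

# Fragments (147 bp) centred on the given dyads.
frags_at <- function(dyads, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = dyads - 73L, end = dyads + 74L)
}

nucs_at <- function(dyads, chrom = "chr1") {
  tibble::tibble(chrom = chrom, dyad = as.integer(dyads),
                 rc = 10L, occupancy = 1, fuzziness = 0)
}

gene_at <- function(tss, strand = "+", chrom = "chr1", id = "g1") {
  tibble::tibble(gene_id = id, chrom = chrom, strand = strand,
                 tss = as.integer(tss),
                 tes = as.integer(tss + if (strand == "+") 4000L else -4000L))
}

peaks_tbl <- function(starts, ends, scores, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), score = scores)
}

# Binarized track on a single-chromosome grid from a 0/1 vector.
track_from_bits <- function(bits, bin = 200L, chrom = "chr1") {
  n <- length(bits)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1L) * bin,
                 end = seq_len(n) * bin, count = as.integer(bits),
                 on = as.logical(bits))
}
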