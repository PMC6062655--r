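# Small in-code fixtures shared across test files.

# Pooled-count tibble from explicit vectors.
make_counts <- function(chrom, pos, n_major, n_minor) {
  tibble::tibble(chrom = chrom, pos = pos,
                 ref = "A", alt = "C",
                 n_ref = n_major, n_alt = n_minor,
                 n_major = pmax(n_major, n_minor),
                 n_minor = pmin(n_major, n_minor),
                 major_allele = "ref")
}

# Write a small VCF from explicit record lines (GT-only, 4.2 header).
write_test_vcf <- function(path, records, samples = c("s1", "s2"),
                           contigs = c(chr1 = 1e6)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Brute-force window sums: loop over every (window, site) pair.
brute_window_sums <- function(counts, windows) {
  out <- windows
  out$n_snps <- 0L; out$sum_major <- 0; out$sum_minor <- 0
  for (i in seq_len(nrow(windows))) {
    hit <- counts$chrom == windows$chrom[i] &
      counts$pos >= windows$start[i] & counts$pos <= windows$end[i]
    out$n_snps[i] <- sum(hit)
    out$sum_major[i] <- sum(counts$n_major[hit])
    out$sum_minor[i] <- sum(counts$n_minor[hit])
  }
  out
}

# Brute-force pooled counts from a character GT matrix.
brute_pool <- function(gt) {
  n_ref <- integer(nrow(gt)); n_alt <- integer(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      g <- gt[i, j]
      if (is.na(g)) next
      for (a in strsplit(g, "[/|]")[[1]]) {
        if (a == "0") n_ref[i] <- n_ref[i] + 1L
        if (a == "1") n_alt[i] <- n_alt[i] + 1L
      }
    }
  }
  list(n_major = pmax(n_ref, n_alt), n_minor = pmin(n_ref, n_alt))
}
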