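#' Read bi-allelic SNPs from a VCF
#'
#' Parses a multi-sample VCF (via vcfR), keeps bi-allelic SNP records on the
#' chromosome whitelist, and reports how many records each filter dropped.
#' Multi-allelic records (comma in ALT), indels/non-SNVs (REF or ALT not a
#' single A/C/G/T) and off-whitelist contigs are removed; the tallies are
#' attached as the `dropped` element and logged.
#'
#' @param path VCF file (plain or bgzipped).
#' @param chroms optional character vector of chromosomes to keep
#'   (`NULL` = keep all).
#' @param samples optional character vector of sample IDs that must be
#'   present; a missing ID is a hard error naming it.
#' @return object of class `biallelic_snps`: list with `sites` (tibble
#'   `chrom`, `pos`, `ref`, `alt`), `gt` (character matrix sites x samples),
#'   `samples`, and `dropped` (named counts).
#' @export
read_biallelic_snps <- function(path, chroms = NULL, samples = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("Malformed VCF '", path, "': ", conditionMessage(e)))
  )
  fix <- vcf@fix
  have <- colnames(vcf@gt)[-1]
  if (!is.null(samples)) {
    missing <- setdiff(samples, have)
    if (length(missing)) {
      abort(paste0("Sample(s) not present in ", path, ": ",
                   paste(missing, collapse = ", ")))
    }
  }
  chrom <- fix[, "CHROM"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  snv <- !multi & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  not_snv <- !multi & !snv
  off <- if (is.null(chroms)) rep(FALSE, length(chrom)) else !chrom %in% chroms
  keep <- snv & !off
  dropped <- c(multiallelic = sum(multi),
               not_snp = sum(not_snv & !off),
               off_whitelist = sum(off & !multi & !not_snv))
  inform(sprintf(
    "%s: kept %d bi-allelic SNPs (dropped %d multi-allelic, %d non-SNP, %d off-whitelist)",
    basename(path), sum(keep), dropped[["multiallelic"]], dropped[["not_snp"]],
    dropped[["off_whitelist"]]))
  sites <- tibble(chrom = chrom[keep], pos = as.numeric(fix[keep, "POS"]),
                  ref = ref[keep], alt = alt[keep])
  gt <- vcfR::extract.gt(vcf)[keep, , drop = FALSE]
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  structure(list(sites = sites[ord, ], gt = gt[ord, , drop = FALSE],
                 samples = have, dropped = dropped),
            class = "biallelic_snps")
}

#' @export
print.biallelic_snps <- function(x, ...) {
  cat(sprintf("<biallelic_snps> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Pool per-site allele counts within one population
#'
#' Tallies called REF and ALT alleles across a population's samples at each
#' site and labels the more frequent allele the major one. Ties are broken
#' by calling the reference allele major (the choice cannot change Hp).
#' Missing alleles are simply absent from both counts, so the denominator is
#' the number of observed alleles; sites with zero called alleles are dropped
#' and counted. Sites monomorphic within the population (`n_minor` = 0) are
#' retained by default — a site fixed in one population is exactly the signal
#' a sweep scan looks for — but can be dropped for sensitivity analysis.
#'
#' @param snps a `biallelic_snps` object from [read_biallelic_snps()], or a
#'   list with `sites` and a genotype matrix `gt` (character GT strings or
#'   integer dosages 0/1/2 with NA).
#' @param samples sample IDs forming the population (`NULL` = all).
#' @param drop_monomorphic drop sites with `n_minor` = 0 within this
#'   population (default `FALSE`).
#' @return tibble of per-site pooled counts: `chrom`, `pos`, `ref`, `alt`,
#'   `n_ref`, `n_alt`, `n_major`, `n_minor`, `major_allele` ("ref"/"alt").
#' @export
pool_allele_counts <- function(snps, samples = NULL, drop_monomorphic = FALSE) {
  gt <- snps$gt
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing)) {
      abort(paste0("Sample(s) not in genotype matrix: ",
                   paste(missing, collapse = ", ")))
    }
    gt <- gt[, samples, drop = FALSE]
  }
  if (is.character(gt)) {
    # count '0' and '1' allele characters per GT string; '.' contributes nothing
    n0 <- nchar(gsub("[^0]", "", gt))
    n1 <- nchar(gsub("[^1]", "", gt))
    dim(n0) <- dim(gt); dim(n1) <- dim(gt)
    n0[is.na(gt)] <- 0L; n1[is.na(gt)] <- 0L
    n_ref <- rowSums(n0); n_alt <- rowSums(n1)
  } else {
    called <- !is.na(gt)
    galt <- gt; galt[!called] <- 0L
    n_alt <- rowSums(galt)
    n_ref <- 2L * rowSums(called) - n_alt
  }
  out <- snps$sites |>
    mutate(n_ref = as.integer(n_ref), n_alt = as.integer(n_alt))
  empty <- out$n_ref + out$n_alt == 0L
  if (any(empty)) {
    inform(sprintf("Dropped %d site(s) with no called alleles in this population.",
                   sum(empty)))
    out <- out[!empty, ]
  }
  out <- out |>
    mutate(
      n_major = pmax(.data$n_ref, .data$n_alt),
      n_minor = pmin(.data$n_ref, .data$n_alt),
      major_allele = if_else(.data$n_alt > .data$n_ref, "alt", "ref")
    )
  if (drop_monomorphic) out <- filter(out, .data$n_minor > 0L)
  out
}

#' Read a VCF and pool counts for each population
#'
#' Convenience wrapper: [read_biallelic_snps()] then [pool_allele_counts()]
#' per population.
#'
#' @param path VCF file.
#' @param populations named list of sample-ID vectors, or a two-column
#'   data frame (`sample`, `population`), or `NULL` to treat all samples as
#'   one population named after the file.
#' @param chroms chromosome whitelist (`NULL` = all).
#' @param drop_monomorphic see [pool_allele_counts()].
#' @return named list of per-population pooled-count tibbles.
#' @export
read_population_counts <- function(path, populations = NULL, chroms = NULL,
                                   drop_monomorphic = FALSE) {
  if (is.data.frame(populations)) {
    populations <- split(populations$sample, populations$population)
  }
  all_samples <- if (is.null(populations)) NULL else unlist(populations, use.names = FALSE)
  snps <- read_biallelic_snps(path, chroms = chroms, samples = all_samples)
  if (is.null(populations)) {
    populations <- setNames(list(snps$samples),
                            sub("\\.vcf(\\.gz)?$", "", basename(path)))
  }
  map(populations, function(s) {
    pool_allele_counts(snps, samples = s, drop_monomorphic = drop_monomorphic)
  })
}
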