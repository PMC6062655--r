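#' Configuration for the synthetic-population generator
#'
#' Builds and validates the configuration that drives [simulate_sites()],
#' [genotype_samples()] and [simulate_study()]. The defaults describe a small
#' two-chromosome genome whose downstream window statistics resemble a
#' village-chicken-style resequencing panel: ~14 SNPs/kb, a folded neutral
#' background with minor-allele frequencies uniform on \[0.05, 0.5\], a 2%
#' missing-genotype rate, and three planted sweeps of 40, 100 and 200 kb in
#' which the minor-allele frequency collapses below 0.02.
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length (bp).
#' @param n_samples diploid samples per population.
#' @param snp_density expected SNPs per kb (> 0).
#' @param maf_min,maf_max support of the folded background minor-allele
#'   frequency distribution (uniform).
#' @param sweeps tibble/data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and `maf_ceiling` in \[0, 0.5\]; an optional
#'   `population` column restricts a sweep to one population (NA = planted in
#'   every population). `NULL` means no sweeps.
#' @param missing_rate probability a genotype call is missing, in \[0, 1).
#' @param populations character vector of population labels.
#' @param seed master integer seed; each population derives its own RNG
#'   stream from it, so adding a population leaves the others byte-identical.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_samples = 10L,
                       snp_density = 14,
                       maf_min = 0.05, maf_max = 0.5,
                       sweeps = default_sweeps(),
                       missing_rate = 0.02,
                       populations = c("popA", "popB"),
                       seed = 1L) {
  check_chrom_lengths(chrom_lengths)
  if (n_samples < 1) abort("`n_samples` must be a positive integer.")
  if (!is.finite(snp_density) || snp_density <= 0) abort("`snp_density` must be finite and > 0.")
  if (!(maf_min >= 0 && maf_min < maf_max && maf_max <= 0.5)) {
    abort("Need 0 <= maf_min < maf_max <= 0.5 for the background MAF support.")
  }
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (!length(populations) || anyDuplicated(populations)) {
    abort("`populations` must be non-empty unique labels.")
  }
  if (!is.null(sweeps)) {
    sweeps <- as_tibble(sweeps)
    needed <- c("chrom", "start", "end", "maf_ceiling")
    if (!all(needed %in% names(sweeps))) {
      abort("`sweeps` needs columns chrom, start, end, maf_ceiling.")
    }
    if (!"population" %in% names(sweeps)) sweeps$population <- NA_character_
    bad <- !sweeps$chrom %in% names(chrom_lengths)
    if (any(bad)) abort(paste0("Sweep on unknown chromosome: ", sweeps$chrom[bad][1]))
    within <- sweeps$start >= 1 & sweeps$end <= chrom_lengths[sweeps$chrom] &
      sweeps$start <= sweeps$end
    if (!all(within)) abort("Every sweep interval must lie within its chromosome.")
    if (any(sweeps$maf_ceiling < 0 | sweeps$maf_ceiling > 0.5)) {
      abort("Sweep `maf_ceiling` must lie in [0, 0.5].")
    }
    if (any(sweeps$maf_ceiling >= maf_min)) {
      abort("Sweep `maf_ceiling` must be below `maf_min`, else planted sweeps cannot depress heterozygosity.")
    }
  }
  structure(list(
    chrom_lengths = chrom_lengths, n_samples = as.integer(n_samples),
    snp_density = snp_density, maf_min = maf_min, maf_max = maf_max,
    sweeps = sweeps, missing_rate = missing_rate,
    populations = populations, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default planted sweeps for the bundled study conditions
#'
#' Three sweeps of 40, 100 and 200 kb with minor-allele frequencies capped at
#' 0.02, aligned to the 10-kb window lattice.
#'
#' @return tibble with columns `chrom`, `start`, `end`, `maf_ceiling`.
#' @export
default_sweeps <- function() {
  tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000001, 3000001, 2500001),
    end   = c(1040000, 3200000, 2600000),
    maf_ceiling = 0.02
  )
}

sweeps_for_population <- function(config, population) {
  sw <- config$sweeps
  if (is.null(sw) || nrow(sw) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  maf_ceiling = numeric(), population = character()))
  }
  sw[is.na(sw$population) | sw$population == population, , drop = FALSE]
}

#' Simulate per-site allele frequencies for one population
#'
#' Draws SNP positions and true alternate-allele frequencies along each
#' chromosome. Site counts are Poisson(`snp_density` x length/kb); positions
#' are uniform without replacement, so strictly increasing after sorting.
#' Background sites draw a folded minor-allele frequency uniform on
#' \[`maf_min`, `maf_max`\] and assign it to REF or ALT with equal
#' probability; sites inside a planted sweep draw the MAF uniform on
#' \[0, `maf_ceiling`\] instead, which collapses heterozygosity there.
#' Frequencies are i.i.d. across sites (no linkage): the downstream scan
#' consumes only per-site pooled counts.
#'
#' @param config a [sim_config()].
#' @param population population label whose RNG stream to use (defaults to
#'   the first configured population).
#' @return tibble with columns `chrom`, `pos`, `ref`, `alt`, `freq_alt`,
#'   `in_sweep`, sorted by chromosome then position.
#' @export
simulate_sites <- function(config, population = config$populations[1]) {
  stopifnot(inherits(config, "sim_config"))
  if (!population %in% config$populations) {
    abort(paste0("Unknown population: ", population))
  }
  sw <- sweeps_for_population(config, population)
  if (nrow(sw) > 1) {
    for (ch in unique(sw$chrom)) {
      s <- sw[sw$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        abort(paste0("Overlapping sweep intervals on chromosome ", ch,
                     ": sweeps must be disjoint within a chromosome."))
      }
    }
  }
  idx <- match(population, config$populations)
  withr::with_seed(derive_pop_seed(config$seed, idx), {
    per_chrom <- imap(config$chrom_lengths, function(len, ch) {
      n <- rpois(1L, config$snp_density * len / 1000)
      n <- min(n, len)  # cannot place more SNPs than positions
      pos <- sort(sample.int(len, n))
      maf <- runif(n, config$maf_min, config$maf_max)
      in_sweep <- rep(FALSE, n)
      swc <- sw[sw$chrom == ch, ]
      if (nrow(swc)) {
        for (k in seq_len(nrow(swc))) {
          hit <- pos >= swc$start[k] & pos <= swc$end[k]
          in_sweep[hit] <- TRUE
          maf[hit] <- runif(sum(hit), 0, swc$maf_ceiling[k])
        }
      }
      # fold direction: the minor allele is ALT or REF with equal probability
      freq_alt <- ifelse(runif(n) < 0.5, maf, 1 - maf)
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt_shift <- sample.int(3L, n, replace = TRUE)
      bases <- c("A", "C", "G", "T")
      alt <- bases[((match(ref, bases) - 1L + alt_shift) %% 4L) + 1L]
      tibble(chrom = ch, pos = pos, ref = ref, alt = alt,
             freq_alt = freq_alt, in_sweep = in_sweep)
    })
    list_rbind(unname(per_chrom))
  })
}

#' Draw diploid genotypes at simulated sites
#'
#' Each genotype is the sum of two independent Bernoulli draws at the site's
#' alternate-allele frequency (Hardy-Weinberg sampling), then masked missing
#' independently at `missing_rate`.
#'
#' @param sites tibble from [simulate_sites()] (needs a `freq_alt` column).
#' @param n_samples number of diploid samples (> 0).
#' @param missing_rate per-genotype missing probability in \[0, 1).
#' @param seed integer seed for this draw.
#' @return integer matrix (sites x samples) of ALT-allele dosages 0/1/2 with
#'   `NA` for missing calls.
#' @export
genotype_samples <- function(sites, n_samples, missing_rate = 0, seed = 1L) {
  if (n_samples <= 0) abort("`n_samples` must be > 0.")
  if (missing_rate >= 1) abort("`missing_rate` = 1 leaves no callable genotypes.")
  if (any(sites$freq_alt < 0 | sites$freq_alt > 1)) abort("Frequencies must lie in [0, 1].")
  n <- nrow(sites)
  withr::with_seed(as.integer(seed), {
    g <- matrix(rbinom(n * n_samples, 2L, rep(sites$freq_alt, n_samples)),
                nrow = n, ncol = n_samples)
    if (missing_rate > 0) {
      g[runif(n * n_samples) < missing_rate] <- NA_integer_
    }
    g
  })
}

#' Write genotypes as a VCF 4.2 file
#'
#' Emits bi-allelic SNP records with a GT-only FORMAT and contig headers, the
#' minimal layout the ingest side consumes. Missing genotypes are written as
#' `./.`.
#'
#' @param sites site tibble (`chrom`, `pos`, `ref`, `alt`), sorted by
#'   chromosome then position.
#' @param genotypes matrix from [genotype_samples()] (sites x samples).
#' @param path output path (plain text).
#' @param chrom_lengths named vector for `##contig` headers.
#' @param sample_names column names; defaults to `S1..Sn`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, genotypes, path, chrom_lengths,
                      sample_names = NULL) {
  n <- nrow(sites)
  if (n > 0) {
    ord <- order(match(sites$chrom, names(chrom_lengths)), sites$pos)
    if (!identical(ord, seq_len(n))) abort("Sites must be sorted by chromosome then position.")
    stopifnot(nrow(genotypes) == n)
  }
  ns <- if (n > 0) ncol(genotypes) else length(sample_names)
  if (is.null(sample_names)) sample_names <- paste0("S", seq_len(ns))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolhet-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[genotypes + 1L], nrow = n)
  gt[is.na(genotypes)] <- "./."
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write planted-sweep truth intervals as BED
#'
#' Converts the 1-based inclusive internal intervals to BED's 0-based
#' half-open convention and stores each sweep's MAF ceiling in the name
#' column.
#'
#' @param truth a `sim_truth` object or a sweep tibble
#'   (`chrom`, `start`, `end`, `maf_ceiling`).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  sw <- if (inherits(truth, "sim_truth")) truth$sweeps else as_tibble(truth)
  if (is.null(sw) || nrow(sw) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  sw <- sw[order(sw$chrom, sw$start), ]
  writeLines(paste(sw$chrom, format(sw$start - 1, scientific = FALSE, trim = TRUE),
                   format(sw$end, scientific = FALSE, trim = TRUE),
                   sw$maf_ceiling, sep = "\t"), path)
  invisible(path)
}

#' Read a truth BED back into 1-based intervals
#'
#' @param path BED written by [write_truth()].
#' @return tibble `chrom`, `start`, `end` (1-based inclusive), `maf_ceiling`.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  maf_ceiling = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)) + 1,
    end = as.numeric(vapply(parts, `[[`, "", 3L)),
    maf_ceiling = as.numeric(vapply(parts, `[[`, "", 4L))
  )
}

#' Simulate one population end to end
#'
#' Runs [simulate_sites()] and [genotype_samples()] on the population's
#' derived RNG stream and, if `out_dir` is given, writes the VCF and truth
#' BED.
#'
#' @param config a [sim_config()].
#' @param population population label.
#' @param out_dir optional output directory.
#' @return list with `sites`, `genotypes`, `sample_names`, `truth`
#'   (a `sim_truth`: sweeps, per-chromosome realized SNP counts, seed), and
#'   file paths when written.
#' @export
simulate_population <- function(config, population = config$populations[1],
                                out_dir = NULL) {
  sites <- simulate_sites(config, population)
  idx <- match(population, config$populations)
  geno_seed <- derive_pop_seed(config$seed, idx + 1000L)
  geno <- genotype_samples(sites, config$n_samples, config$missing_rate,
                           seed = geno_seed)
  sample_names <- sprintf("%s_%02d", population, seq_len(config$n_samples))
  realized <- sites |> count(.data$chrom, name = "n_snps")
  if (any(realized$n_snps == 0) || !all(names(config$chrom_lengths) %in% realized$chrom)) {
    abort("A simulated chromosome realized zero SNPs; increase `snp_density`.")
  }
  truth <- structure(list(sweeps = sweeps_for_population(config, population),
                          realized_snps = realized,
                          seed = config$seed),
                     class = "sim_truth")
  out <- list(sites = sites, genotypes = geno, sample_names = sample_names,
              truth = truth, population = population)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$vcf <- file.path(out_dir, paste0(population, ".vcf"))
    out$truth_bed <- file.path(out_dir, paste0(population, ".truth.bed"))
    write_vcf(sites, geno, out$vcf, config$chrom_lengths, sample_names)
    write_truth(truth, out$truth_bed)
  }
  out
}

#' Simulate every configured population
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (one VCF + truth BED per
#'   population).
#' @return named list of [simulate_population()] results.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  setNames(
    map(config$populations, simulate_population, config = config,
        out_dir = out_dir),
    config$populations
  )
}
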