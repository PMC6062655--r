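#' Round half away from zero
#'
#' Rounds to the nearest integer with halves going up (2.5 -> 3), the
#' convention used for the per-region SNP-density summaries. Base R's
#' `round()` rounds half to even and would give different densities for
#' counts that land exactly on a half.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Derive an independent RNG stream seed for population `index` (1-based) from
# the master seed. The rule is fixed so adding a population never perturbs the
# streams of existing ones; the modulus keeps the result a valid 32-bit seed.
derive_pop_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 11113 * as.numeric(index)) %% 2147483647)
}

# Validate a named numeric vector of chromosome lengths (bp).
check_chrom_lengths <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named numeric vector (name -> bp).")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    abort("`chrom_lengths` has duplicated chromosome names.")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths < 1)) {
    abort("All chromosome lengths must be finite and >= 1 bp.")
  }
  chrom_lengths
}

#' Read a two-column chromosome-length table
#'
#' @param path TSV with columns `chrom` and `length` (no header required;
#'   a header row is auto-detected).
#' @return named numeric vector of lengths in bp.
#' @export
read_chrom_lengths <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 2) abort("Chromosome-length table needs two columns: chrom, length.")
  if (is.na(suppressWarnings(as.numeric(tab[[2]][1])))) tab <- tab[-1, ]
  check_chrom_lengths(setNames(as.numeric(tab[[2]]), as.character(tab[[1]])))
}

#' Read a two-column sample-to-population map
#'
#' @param path TSV with columns `sample` and `population`.
#' @return tibble with columns `sample`, `population`.
#' @export
read_population_map <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 2) abort("Population map needs two columns: sample, population.")
  if (identical(tolower(as.character(tab[1, 1])), "sample")) tab <- tab[-1, ]
  out <- tibble(sample = as.character(tab[[1]]), population = as.character(tab[[2]]))
  if (anyDuplicated(out$sample)) abort("Duplicate sample IDs in population map.")
  out
}
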