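#' Significant windows of a scan
#'
#' A window is significant when it passed the min-SNP filter and its Z(Hp)
#' is at or below the threshold (the boundary value itself is significant).
#'
#' @param scan an `hp_scan`, or a window tibble with `zhp` and
#'   `passes_filter` columns.
#' @param z_threshold significance threshold; defaults to the scan's
#'   configured value (or -4 for a bare tibble).
#' @return tibble of significant windows.
#' @export
call_significant <- function(scan, z_threshold = NULL) {
  if (inherits(scan, "hp_scan")) {
    z_threshold <- z_threshold %||% scan$config$z_threshold
    windows <- scan$windows
  } else {
    z_threshold <- z_threshold %||% -4
    windows <- scan
  }
  windows |>
    filter(.data$passes_filter, !is.na(.data$zhp), .data$zhp <= z_threshold)
}

#' Merge significant windows into candidate sweep regions
#'
#' Maximal runs of significant windows that overlap or abut (or sit within
#' `max_gap` bp of each other) on one chromosome merge into a single region
#' spanning their union. With full windows of width w sliding by s, a run of
#' k windows spans w + (k - 1) * s, so region sizes fall on an s-sized
#' lattice. Merging is idempotent and conserves the window count.
#'
#' @param sig_windows tibble from [call_significant()] (needs `chrom`,
#'   `start`, `end`; `zhp` used for region statistics when present).
#' @param population label attached to the output rows.
#' @param max_gap bp allowed between consecutive windows (0 = overlap/abut).
#' @return tibble of regions: `chrom`, `start`, `end`, `span`, `n_windows`,
#'   `mean_zhp`, `sd_zhp` (0 for single-window regions), `population`.
#' @export
merge_regions <- function(sig_windows, population = NA_character_, max_gap = 0) {
  if (nrow(sig_windows) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  span = numeric(), n_windows = integer(),
                  mean_zhp = numeric(), sd_zhp = numeric(),
                  population = character()))
  }
  if (!"zhp" %in% names(sig_windows)) sig_windows$zhp <- NA_real_
  if (!"n_windows" %in% names(sig_windows)) sig_windows$n_windows <- 1L
  sig_windows |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(new_run = .data$start > cummax(lag(.data$end, default = -Inf)) + 1 + max_gap,
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = sum(.data$n_windows),
              mean_zhp = mean(.data$zhp),
              sd_zhp = if (sum(.data$n_windows) > 1) sd(.data$zhp) else 0,
              .groups = "drop") |>
    mutate(span = .data$end - .data$start + 1,
           sd_zhp = if_else(is.na(.data$sd_zhp), 0, .data$sd_zhp),
           population = population) |>
    select("chrom", "start", "end", "span", "n_windows", "mean_zhp",
           "sd_zhp", "population") |>
    arrange(.data$chrom, .data$start)
}

#' SNP density on the nominal 10-kb length lattice
#'
#' Region lengths from a w = 20 kb / s = 10 kb scan are nominally multiples
#' of 10 kb but real coordinates come out a few bp short (e.g. a 19,988-bp
#' single-window region is nominally 20 kb). The density is the SNP count
#' divided by the nominal length in kb — the span rounded to the nearest
#' 10 kb — rounded half-up to an integer.
#'
#' @param n_snps SNP count(s) in the region.
#' @param span_bp region span(s) in bp (end - start + 1).
#' @return integer SNPs/kb.
#' @export
snps_per_kb <- function(n_snps, span_bp) {
  if (any(span_bp <= 0)) abort("Region span must be positive.")
  nominal_kb <- pmax(round_half_up(span_bp / 10000), 1) * 10
  round_half_up(n_snps / nominal_kb)
}

#' Per-region SNP counts and densities
#'
#' Counts the distinct pooled sites falling in each region (inclusive
#' coordinates) and reports the rounded SNPs/kb on the nominal length
#' lattice alongside the raw count.
#'
#' @param regions region tibble from [merge_regions()].
#' @param counts pooled site tibble for the same population (needs `chrom`,
#'   `pos`).
#' @return `regions` with `n_snps` and `snps_per_kb` appended.
#' @export
region_snp_density <- function(regions, counts) {
  if (nrow(regions) == 0) {
    return(mutate(regions, n_snps = integer(), snps_per_kb = numeric()))
  }
  if (any(regions$end < regions$start)) abort("Region with non-positive length.")
  n <- vapply(seq_len(nrow(regions)), function(i) {
    pos <- counts$pos[counts$chrom == regions$chrom[i]]
    pos <- sort(pos)
    findInterval(regions$end[i], pos) - findInterval(regions$start[i] - 1, pos)
  }, integer(1))
  regions |>
    mutate(n_snps = n, snps_per_kb = snps_per_kb(n, .data$span))
}

#' Call and merge sweep regions from a scan
#'
#' Convenience wrapper: [call_significant()], [merge_regions()] and
#' [region_snp_density()] in one step.
#'
#' @param scan an `hp_scan`.
#' @param z_threshold,max_gap overrides of the scan's configured values.
#' @return region tibble with SNP densities.
#' @export
sweep_regions <- function(scan, z_threshold = NULL, max_gap = NULL) {
  stopifnot(inherits(scan, "hp_scan"))
  sig <- call_significant(scan, z_threshold)
  regions <- merge_regions(sig, population = scan$population,
                           max_gap = max_gap %||% scan$config$max_merge_gap)
  region_snp_density(regions, scan$counts)
}

#' Annotate regions with overlapping gene intervals
#'
#' Joins candidate regions against a user-supplied gene interval table (for
#' example read from a BED or GFF3 file with `rtracklayer::import`); no
#' annotation database is bundled.
#'
#' @param regions region tibble (1-based inclusive `chrom`, `start`, `end`).
#' @param genes tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   a `gene` name column.
#' @return `regions` with a `genes` column (comma-separated overlapping gene
#'   names, `NA` when none).
#' @export
annotate_regions <- function(regions, genes) {
  if (nrow(regions) == 0) return(mutate(regions, genes = character()))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  # disjoint seqlevels between regions and gene table simply mean no overlap
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, gg))
  ann <- rep(NA_character_, nrow(regions))
  if (length(hits)) {
    by_region <- split(genes$gene[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    for (q in names(by_region)) {
      ann[as.integer(q)] <- paste(unique(by_region[[q]]), collapse = ",")
    }
  }
  mutate(regions, genes = ann)
}

#' Write regions as a BED file
#'
#' Converts 1-based inclusive region coordinates to BED 0-based half-open.
#'
#' @param regions region tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- if (nrow(regions)) {
    name <- if ("population" %in% names(regions)) regions$population else "."
    score <- if ("mean_zhp" %in% names(regions)) sprintf("%.4f", regions$mean_zhp) else "."
    paste(regions$chrom,
          format(regions$start - 1, scientific = FALSE, trim = TRUE),
          format(regions$end, scientific = FALSE, trim = TRUE),
          name, score, sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
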