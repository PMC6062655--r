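#' Scan configuration
#'
#' Parameters of the sliding-window pooled-heterozygosity scan. Defaults are
#' the standard choices for this statistic: 20-kb windows sliding by 10 kb,
#' at least 50 SNPs per analyzed window, and a genome-wide significance
#' threshold of Z(Hp) <= -4.
#'
#' @param window_size window width in bp.
#' @param step slide in bp (0 < step <= window_size).
#' @param min_snps minimum SNPs for a window to enter the Z transform
#'   (boundary inclusive: a window with exactly `min_snps` is kept).
#' @param z_threshold call windows significant when Z(Hp) <= this value
#'   (inclusive).
#' @param max_merge_gap bp gap allowed when merging significant windows into
#'   regions; 0 = windows must overlap or abut.
#' @param filter_before_z if `TRUE` (default) the min-SNP exclusion is
#'   applied before the genome-wide mean/SD are computed.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_size = 20000L, step = 10000L, min_snps = 50L,
                        z_threshold = -4, max_merge_gap = 0L,
                        filter_before_z = TRUE) {
  if (!(step > 0 && step <= window_size)) abort("Need 0 < step <= window_size.")
  if (min_snps < 1) abort("`min_snps` must be >= 1.")
  if (!is.finite(z_threshold)) abort("`z_threshold` must be finite.")
  if (max_merge_gap < 0) abort("`max_merge_gap` must be >= 0.")
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 min_snps = as.integer(min_snps), z_threshold = z_threshold,
                 max_merge_gap = as.integer(max_merge_gap),
                 filter_before_z = isTRUE(filter_before_z)),
            class = "scan_config")
}

#' Tile chromosomes with sliding windows
#'
#' Windows are anchored at position 1 and advance by `step`; a terminal
#' window truncated by the chromosome end is emitted only if it is longer
#' than one step, so the last tile is never a bare step-sized stub.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param config a [scan_config()].
#' @return tibble `chrom`, `start`, `end` (1-based inclusive), ordered.
#' @export
make_windows <- function(chrom_lengths, config = scan_config()) {
  check_chrom_lengths(chrom_lengths)
  w <- config$window_size; s <- config$step
  per_chrom <- imap(chrom_lengths, function(len, ch) {
    start <- seq(1, len, by = s)
    end <- pmin(start + w - 1, len)
    size <- end - start + 1
    keep <- size == w | size > s
    tibble(chrom = ch, start = start[keep], end = end[keep])
  })
  list_rbind(unname(per_chrom))
}

#' Pooled heterozygosity of one window
#'
#' Hp = 2 * S_maj * S_min / (S_maj + S_min)^2, where S_maj and S_min are the
#' window sums of per-site major and minor allele counts. Equivalently
#' Hp = 2 p (1 - p) with p the pooled major-allele fraction, so
#' 0 <= Hp <= 0.5 with the maximum reached only when the sums are equal.
#'
#' @param sum_major,sum_minor window sums of major/minor allele counts.
#' @return Hp; `NaN` when the window holds no alleles.
#' @export
hp_statistic <- function(sum_major, sum_minor) {
  tot <- sum_major + sum_minor
  2 * sum_major * sum_minor / tot^2
}

#' Window-level pooled-heterozygosity statistics
#'
#' Assigns every pooled site to each window containing it (windows overlap
#' when `step < window_size`) and computes per-window SNP counts, allele-count
#' sums and Hp. Windows with zero sites get `NA` Hp.
#'
#' @param counts pooled-count tibble from [pool_allele_counts()].
#' @param windows window tibble from [make_windows()].
#' @return `windows` with `n_snps`, `sum_major`, `sum_minor`, `hp` appended.
#' @export
window_hp <- function(counts, windows) {
  per_chrom <- map(split(seq_len(nrow(windows)), windows$chrom), function(idx) {
    ch <- windows$chrom[idx[1]]
    sites <- counts[counts$chrom == ch, ]
    sites <- sites[order(sites$pos), ]
    cs_major <- c(0, cumsum(as.numeric(sites$n_major)))
    cs_minor <- c(0, cumsum(as.numeric(sites$n_minor)))
    lo <- findInterval(windows$start[idx] - 1, sites$pos)
    hi <- findInterval(windows$end[idx], sites$pos)
    tibble(row = idx,
           n_snps = hi - lo,
           sum_major = cs_major[hi + 1] - cs_major[lo + 1],
           sum_minor = cs_minor[hi + 1] - cs_minor[lo + 1])
  })
  stats <- list_rbind(unname(per_chrom)) |> arrange(.data$row)
  windows |>
    mutate(n_snps = stats$n_snps,
           sum_major = stats$sum_major,
           sum_minor = stats$sum_minor,
           hp = if_else(.data$n_snps > 0,
                        hp_statistic(.data$sum_major, .data$sum_minor),
                        NA_real_))
}

#' Flag windows that meet the minimum-SNP requirement
#'
#' @param window_stats tibble from [window_hp()].
#' @param config a [scan_config()].
#' @return input with a logical `passes_filter` column; errors if no window
#'   passes (a degenerate scan cannot be Z-transformed).
#' @export
apply_min_snp_filter <- function(window_stats, config = scan_config()) {
  out <- window_stats |>
    mutate(passes_filter = !is.na(.data$hp) & .data$n_snps >= config$min_snps)
  if (!any(out$passes_filter)) {
    abort(sprintf("Degenerate scan: no window has >= %d SNPs.", config$min_snps))
  }
  out
}

#' Genome-wide Z transform of window Hp
#'
#' Standardizes window Hp by the genome-wide mean and sample standard
#' deviation (n - 1 denominator) taken over analyzed windows, pooled across
#' chromosomes: Z(Hp) = (Hp - mean) / sd. With the default
#' `filter_before_z = TRUE` the mean/SD are computed over windows passing the
#' min-SNP filter only; Z values are reported only for passing windows either
#' way.
#'
#' @param window_stats tibble with `hp` and `passes_filter` columns.
#' @param config a [scan_config()].
#' @return list with `windows` (adds `zhp`) and `summary` (one-row tibble:
#'   `n_windows`, `n_analyzed`, `n_excluded`, `mean_hp`, `sd_hp`).
#' @export
z_transform <- function(window_stats, config = scan_config()) {
  pass <- window_stats$passes_filter
  base <- if (config$filter_before_z) window_stats$hp[pass] else
    window_stats$hp[!is.na(window_stats$hp)]
  if (length(base) < 2) abort("Need >= 2 analyzed windows to Z-transform.")
  m <- mean(base); s <- sd(base)
  if (!is.finite(s) || s == 0) abort("Zero Hp variance across analyzed windows; cannot Z-transform.")
  windows <- window_stats |>
    mutate(zhp = if_else(pass, (.data$hp - m) / s, NA_real_))
  summary <- tibble(n_windows = nrow(windows),
                    n_analyzed = sum(pass),
                    n_excluded = nrow(windows) - sum(pass),
                    mean_hp = m, sd_hp = s)
  list(windows = windows, summary = summary)
}

#' Run the pooled-heterozygosity scan for one population
#'
#' Tiles the genome, computes windowed Hp from pooled allele counts, applies
#' the minimum-SNP filter and the genome-wide Z transform.
#'
#' @param counts pooled-count tibble from [pool_allele_counts()].
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param config a [scan_config()].
#' @param population optional population label carried into outputs.
#' @return object of class `hp_scan`: list with `windows` (tibble: `chrom`,
#'   `start`, `end`, `n_snps`, `sum_major`, `sum_minor`, `hp`, `zhp`,
#'   `passes_filter`), `summary`, `config`, `population`, `chrom_lengths`,
#'   `counts`.
#' @export
hp_scan <- function(counts, chrom_lengths, config = scan_config(),
                    population = NA_character_) {
  windows <- make_windows(chrom_lengths, config)
  stats <- window_hp(counts, windows) |>
    apply_min_snp_filter(config)
  zt <- z_transform(stats, config)
  structure(list(windows = zt$windows, summary = zt$summary, config = config,
                 population = population, chrom_lengths = chrom_lengths,
                 counts = counts),
            class = "hp_scan")
}

#' @export
print.hp_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hp_scan>%s %d windows (%d analyzed, %d excluded by <%d-SNP rule)\n",
              if (is.na(x$population)) "" else paste0(" [", x$population, "]"),
              s$n_windows, s$n_analyzed, s$n_excluded, x$config$min_snps))
  cat(sprintf("  genome mean Hp = %.4f, SD = %.4f; %d windows at Z(Hp) <= %.3g\n",
              s$mean_hp, s$sd_hp,
              sum(x$windows$zhp <= x$config$z_threshold, na.rm = TRUE),
              x$config$z_threshold))
  invisible(x)
}

#' Tidy a scan into its window table
#'
#' @param x an `hp_scan`.
#' @param ... unused.
#' @return the per-window tibble, one row per window.
#' @export
tidy.hp_scan <- function(x, ...) x$windows

#' One-row scan summary
#'
#' @param x an `hp_scan`.
#' @param ... unused.
#' @return tibble with population, window counts, genome mean/SD of Hp and
#'   the number of significant windows at the configured threshold.
#' @export
glance.hp_scan <- function(x, ...) {
  x$summary |>
    mutate(population = x$population,
           n_significant = sum(x$windows$zhp <= x$config$z_threshold,
                               na.rm = TRUE),
           .before = 1)
}
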