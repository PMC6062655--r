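#' Run the full sweep scan for one or more populations
#'
#' Composes ingest, windowed Hp, Z transform and region calling for each
#' population, and (optionally) writes per-population window TSVs, region
#' BED/TSVs, a study-level summary table and a resolved-config snapshot.
#'
#' @param vcfs VCF path(s): either a single multi-population VCF (then
#'   `populations` assigns samples), or a named character vector with one
#'   VCF per population (names = population labels; all samples in each
#'   file belong to that population).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   also the chromosome whitelist.
#' @param populations for a single joint VCF: a two-column data frame
#'   (`sample`, `population`) or named list of sample IDs.
#' @param config a [scan_config()].
#' @param out_dir optional output directory.
#' @param drop_monomorphic see [pool_allele_counts()].
#' @return object of class `scan_run`: list with `scans` (named `hp_scan`
#'   list), `regions` (named region-tibble list), `summary` (one row per
#'   population: sample count, analyzed windows, mean/SD Hp, significant
#'   windows, region count, excluded windows) and `config`.
#' @export
run_scan <- function(vcfs, chrom_lengths, populations = NULL,
                     config = scan_config(), out_dir = NULL,
                     drop_monomorphic = FALSE) {
  check_chrom_lengths(chrom_lengths)
  chroms <- names(chrom_lengths)
  counts <- list()
  n_samples <- integer()
  if (length(vcfs) > 1 || !is.null(names(vcfs))) {
    if (is.null(names(vcfs)) || anyDuplicated(names(vcfs))) {
      abort("Per-population `vcfs` must be uniquely named by population.")
    }
    for (popn in names(vcfs)) {
      snps <- read_biallelic_snps(vcfs[[popn]], chroms = chroms)
      counts[[popn]] <- pool_allele_counts(snps, drop_monomorphic = drop_monomorphic)
      n_samples[[popn]] <- length(snps$samples)
    }
  } else {
    if (is.null(populations)) abort("A joint VCF needs a `populations` assignment.")
    if (is.data.frame(populations)) {
      populations <- split(populations$sample, populations$population)
    }
    snps <- read_biallelic_snps(vcfs, chroms = chroms,
                                samples = unlist(populations, use.names = FALSE))
    for (popn in names(populations)) {
      counts[[popn]] <- pool_allele_counts(snps, samples = populations[[popn]],
                                           drop_monomorphic = drop_monomorphic)
      n_samples[[popn]] <- length(populations[[popn]])
    }
  }
  scans <- imap(counts, function(ct, popn) {
    hp_scan(ct, chrom_lengths, config, population = popn)
  })
  regions <- map(scans, sweep_regions)
  summary <- imap(scans, function(sc, popn) {
    glance(sc) |> mutate(n_samples = n_samples[[popn]],
                         n_regions = nrow(regions[[popn]]),
                         .after = "population")
  }) |> list_rbind()
  run <- structure(list(scans = scans, regions = regions, summary = summary,
                        config = config, chrom_lengths = chrom_lengths),
                   class = "scan_run")
  if (!is.null(out_dir)) write_scan_outputs(run, out_dir)
  run
}

#' @export
print.scan_run <- function(x, ...) {
  cat(sprintf("<scan_run> %d population(s)\n", length(x$scans)))
  print(x$summary)
  invisible(x)
}

write_scan_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (popn in names(run$scans)) {
    readr::write_tsv(run$scans[[popn]]$windows,
                     file.path(out_dir, paste0(popn, ".windows.tsv")))
    readr::write_tsv(run$regions[[popn]],
                     file.path(out_dir, paste0(popn, ".regions.tsv")))
    write_regions_bed(run$regions[[popn]],
                      file.path(out_dir, paste0(popn, ".regions.bed")))
  }
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"))
  yaml::write_yaml(c(unclass(run$config),
                     list(chrom_lengths = as.list(run$chrom_lengths))),
                   file.path(out_dir, "resolved_config.yaml"))
  invisible(out_dir)
}

#' Compare scans across populations
#'
#' Window-level region sharing plus Venn-style shared-SNP counts for the
#' populations of a [run_scan()] result (or an explicit named list of
#' `hp_scan` objects). All scans must share the same configuration and
#' chromosome table.
#'
#' @param run a `scan_run`, or a named list of >= 2 `hp_scan` objects.
#' @param wild optional wild/outgroup population label (see
#'   [intersect_populations()]).
#' @param out_dir optional directory for `shared_regions.tsv` and
#'   `shared_snp_counts.tsv`.
#' @return list with `shared_regions` (see [intersect_populations()]),
#'   `shared_snps` (see [shared_snp_counts()]) and `class_counts`.
#' @export
run_compare <- function(run, wild = NULL, out_dir = NULL) {
  scans <- if (inherits(run, "scan_run")) run$scans else run
  if (length(scans) < 2) abort("Need >= 2 scans to compare.")
  cfgs <- map(scans, function(s) unclass(s$config))
  if (!all(vapply(cfgs[-1], identical, logical(1), y = cfgs[[1]]))) {
    abort("Scans were produced with different configurations; re-run with one config.")
  }
  chl <- map(scans, function(s) s$chrom_lengths)
  if (!all(vapply(chl[-1], identical, logical(1), y = chl[[1]]))) {
    abort("Scans use different chromosome tables.")
  }
  shared <- intersect_populations(scans, wild = wild)
  venn <- shared_snp_counts(map(scans, function(s) s$counts))
  class_counts <- shared |> count(.data$sharing_class, name = "n_regions")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(shared, file.path(out_dir, "shared_regions.tsv"))
    readr::write_tsv(venn, file.path(out_dir, "shared_snp_counts.tsv"))
  }
  list(shared_regions = shared, shared_snps = venn, class_counts = class_counts)
}

#' Manhattan-plot-ready window table
#'
#' Lays windows out on a cumulative genome coordinate (chromosomes
#' concatenated in table order), with an alternating parity column for the
#' conventional two-tone coloring. The significance threshold is attached
#' as attribute `z_threshold`.
#'
#' @param scan an `hp_scan`, or a window tibble.
#' @param chrom_lengths chromosome lengths; defaults to the scan's.
#' @param z_threshold threshold recorded as metadata; defaults to the
#'   scan's configured value.
#' @return window tibble with `cum_pos` (strictly increasing window
#'   midpoint on the cumulative coordinate), `chrom_index` and `parity`.
#' @export
export_manhattan_table <- function(scan, chrom_lengths = NULL,
                                   z_threshold = NULL) {
  if (inherits(scan, "hp_scan")) {
    chrom_lengths <- chrom_lengths %||% scan$chrom_lengths
    z_threshold <- z_threshold %||% scan$config$z_threshold
    windows <- scan$windows
  } else {
    windows <- scan
    if (is.null(chrom_lengths)) abort("Supply `chrom_lengths` for a bare window table.")
    z_threshold <- z_threshold %||% -4
  }
  empty <- setdiff(names(chrom_lengths), unique(windows$chrom))
  if (length(empty)) {
    warn(paste0("Chromosome(s) without windows skipped: ",
                paste(empty, collapse = ", ")))
  }
  chroms <- names(chrom_lengths)
  offsets <- setNames(cumsum(c(0, as.numeric(chrom_lengths[-length(chrom_lengths)]))),
                      chroms)
  out <- windows |>
    filter(.data$chrom %in% chroms) |>
    mutate(chrom_index = match(.data$chrom, chroms),
           cum_pos = offsets[.data$chrom] + (.data$start + .data$end) / 2,
           parity = .data$chrom_index %% 2L) |>
    arrange(.data$cum_pos)
  attr(out, "z_threshold") <- z_threshold
  out
}

#' Manhattan plot of a scan
#'
#' Z(Hp) along the cumulative genome coordinate with the significance
#' threshold drawn as a dashed line. Sweeps appear as dips below the line
#' (low heterozygosity means strongly negative Z).
#'
#' @param object an `hp_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hp_scan <- function(object, ...) {
  tab <- export_manhattan_table(object)
  thr <- attr(tab, "z_threshold")
  ggplot2::ggplot(tab[!is.na(tab$zhp), ],
                  ggplot2::aes(x = .data$cum_pos / 1e6, y = .data$zhp,
                               colour = factor(.data$parity))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "Genome position (Mb)", y = "Z(Hp)",
                  title = if (!is.na(object$population)) object$population else NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of window Hp values
#'
#' @param scan an `hp_scan`.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_hp_distribution <- function(scan, bins = 60) {
  stopifnot(inherits(scan, "hp_scan"))
  w <- scan$windows |> filter(.data$passes_filter)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$hp)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = scan$summary$mean_hp, linetype = "dashed") +
    ggplot2::labs(x = "Window Hp", y = "Windows") +
    ggplot2::theme_minimal()
}
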