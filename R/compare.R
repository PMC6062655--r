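#' Cross-population sweep-region sharing
#'
#' Intersects significant windows across populations at the window level:
#' a shared region is a maximal interval covered by significant windows in
#' every member population, not merely an overlap of merged regions. The
#' genome is partitioned into maximal segments with a constant set of
#' covering populations (via `GenomicRanges::disjoin`), and each segment is
#' classified by that exact set. With a designated wild population the
#' classes are: `all-domestic+wild` (every population), `all-domestic`
#' (every domestic, wild absent), `domestic+wild` (wild plus some but not
#' all domestics), `domestic-pair` (two or more domestics, wild absent),
#' and `unique` (one population). Each region appears in exactly one class —
#' the largest its covering set satisfies. The result is invariant to the
#' order of the input populations.
#'
#' @param scans named list (>= 2) of `hp_scan` objects, or of significant
#'   window tibbles (`chrom`, `start`, `end`).
#' @param wild optional label of the wild/outgroup population; all others
#'   are treated as domestic.
#' @param min_populations drop segments covered by fewer populations
#'   (default 1 keeps population-unique regions too).
#' @return tibble: `chrom`, `start`, `end`, `span`, one logical presence
#'   column per population, `n_populations`, `populations`
#'   (comma-separated, in input order), `sharing_class`.
#' @export
intersect_populations <- function(scans, wild = NULL, min_populations = 1L) {
  labels <- names(scans)
  if (length(scans) < 2) abort("Need >= 2 populations to intersect.")
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    abort("`scans` must be a named list with unique population labels.")
  }
  if (!is.null(wild) && !wild %in% labels) {
    abort(paste0("`wild` label not among populations: ", wild))
  }
  sig <- map(scans, function(x) {
    if (inherits(x, "hp_scan")) call_significant(x) else as_tibble(x)
  })
  grl <- map(sig, function(w) {
    if (nrow(w) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      w$chrom, IRanges::IRanges(w$start, w$end)))
  })
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  if (length(all_gr) == 0) return(empty_shared_table(labels))
  dj <- GenomicRanges::disjoin(all_gr)
  pres <- vapply(grl, function(g) IRanges::overlapsAny(dj, g),
                 logical(length(dj)))
  if (length(dj) == 1) pres <- matrix(pres, nrow = 1, dimnames = list(NULL, labels))
  mask <- as.integer(pres %*% 2^(seq_along(labels) - 1))
  seg <- tibble(chrom = as.character(GenomicRanges::seqnames(dj)),
                start = GenomicRanges::start(dj),
                end = GenomicRanges::end(dj),
                mask = mask) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(new_run = .data$mask != lag(.data$mask, default = -1L) |
             .data$start != lag(.data$end, default = -2) + 1,
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              mask = .data$mask[1], .groups = "drop") |>
    select(-"run") |>
    arrange(.data$chrom, .data$start)
  pres_mat <- vapply(seq_along(labels),
                     function(i) bitwAnd(seg$mask, bitwShiftL(1L, i - 1L)) > 0L,
                     logical(nrow(seg)))
  if (nrow(seg) == 1) pres_mat <- matrix(pres_mat, nrow = 1)
  colnames(pres_mat) <- labels
  out <- seg |>
    select(-"mask") |>
    mutate(span = .data$end - .data$start + 1)
  out <- bind_cols(out, as_tibble(pres_mat))
  out$n_populations <- rowSums(pres_mat)
  out$populations <- apply(pres_mat, 1L, function(p) paste(labels[p], collapse = ","))
  out$sharing_class <- vapply(seq_len(nrow(out)), function(i) {
    classify_sharing(labels[pres_mat[i, ]], labels, wild)
  }, character(1))
  out |> filter(.data$n_populations >= min_populations)
}

# Largest sharing class satisfied by an exact covering set.
classify_sharing <- function(present, labels, wild) {
  domestic <- if (is.null(wild)) labels else setdiff(labels, wild)
  has_wild <- !is.null(wild) && wild %in% present
  dom_present <- setdiff(present, wild %||% character(0))
  if (setequal(dom_present, domestic) && has_wild) return("all-domestic+wild")
  if (setequal(present, domestic)) return("all-domestic")
  if (has_wild && length(dom_present) >= 1) return("domestic+wild")
  if (length(present) >= 2) return("domestic-pair")
  "unique"
}

empty_shared_table <- function(labels) {
  out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                span = numeric())
  for (l in labels) out[[l]] <- logical()
  out$n_populations <- integer()
  out$populations <- character()
  out$sharing_class <- character()
  out
}

#' Venn-style shared and unique SNP counts across populations
#'
#' Sites are keyed by (chromosome, position, ref, alt). Returns the exact
#' membership partition — one row per combination of populations with the
#' number of sites seen in precisely that combination — from which any
#' union/intersection count follows by inclusion-exclusion.
#'
#' @param site_sets named list of site tibbles (columns `chrom`, `pos`,
#'   `ref`, `alt`), one per population.
#' @return tibble with one logical column per population, `populations`
#'   (comma-separated), `n_populations` and `n_sites` (exact-membership
#'   count). Per-population totals are attached as attribute `totals`.
#' @export
shared_snp_counts <- function(site_sets) {
  labels <- names(site_sets)
  if (is.null(labels) || anyDuplicated(labels)) {
    abort("`site_sets` must be a named list with unique population labels.")
  }
  keys <- map(site_sets, function(s) {
    unique(paste(s$chrom, s$pos, s$ref, s$alt, sep = ":"))
  })
  universe <- unique(unlist(keys, use.names = FALSE))
  pres <- vapply(keys, function(k) universe %in% k, logical(length(universe)))
  if (length(universe) == 1) pres <- matrix(pres, nrow = 1, dimnames = list(NULL, labels))
  pattern <- apply(pres, 1L, paste, collapse = ".")
  combos <- unique(pattern)
  out <- map_dfr(combos, function(cb) {
    row <- pres[match(cb, pattern), , drop = TRUE]
    tibble(!!!setNames(as.list(row), labels),
           populations = paste(labels[row], collapse = ","),
           n_populations = sum(row),
           n_sites = sum(pattern == cb))
  }) |>
    arrange(dplyr::desc(.data$n_populations), .data$populations)
  attr(out, "totals") <- vapply(keys, length, integer(1))
  out
}
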