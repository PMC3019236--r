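#' Gene density per deletion bin
#'
#' Density is the number of loci assigned to a bin divided by the cumulative
#' length (Mb) of the contigs assigned to that bin; the overall density uses
#' the totals.
#'
#' @param loci A locus tibble with a `bin` column, or a precomputed count
#'   table (`bin`, `n_loci`).
#' @param bin_lengths A data frame `bin`, `contig_length_mb` in chromosome
#'   order.
#' @return A `bin_stats` tibble: `bin`, `n_loci`, `contig_length_mb`,
#'   `density`; the overall density and totals are in attribute `"overall"`.
#' @export
bin_density <- function(loci, bin_lengths) {
  bin_lengths <- as_tibble(bin_lengths)
  if (any(bin_lengths$contig_length_mb <= 0)) abort("bin contig length must be > 0")
  counts <- if ("n_loci" %in% names(loci)) {
    as_tibble(loci)[, c("bin", "n_loci")]
  } else {
    loci %>% filter(!is.na(.data$bin)) %>%
      dplyr::count(.data$bin, name = "n_loci")
  }
  out <- bin_lengths %>%
    left_join(counts, by = "bin") %>%
    mutate(n_loci = dplyr::coalesce(.data$n_loci, 0L),
           density = .data$n_loci / .data$contig_length_mb)
  out <- out[, c("bin", setdiff(names(out), "bin"))]
  attr(out, "overall") <- tibble(
    n_loci = sum(out$n_loci),
    contig_length_mb = sum(out$contig_length_mb),
    density = sum(out$n_loci) / sum(out$contig_length_mb)
  )
  class(out) <- c("bin_stats", class(tibble()))
  out
}

#' Normalised gene densities
#'
#' Divides each bin's (unrounded) density by the mean of the per-bin
#' densities, so the normalised values average exactly 1.
#'
#' @param bin_stats A [bin_density()] result (or any tibble with `density`).
#' @return The input with a `normalized_density` column.
#' @export
normalized_density <- function(bin_stats) {
  if (nrow(bin_stats) < 1) abort("need at least one bin")
  bin_stats$normalized_density <- bin_stats$density / mean(bin_stats$density)
  bin_stats
}

#' Distance from each bin's midpoint to the centromere
#'
#' @param bins A data frame with `bin`, `start_bp`, `end_bp` (or `start_mb`,
#'   `end_mb`).
#' @param centromere_bp Centromere position (bp; or Mb if the bins are in
#'   Mb).
#' @return The input with a `midpoint_dist_mb` column (Mb when inputs are
#'   bp).
#' @export
centromere_distance <- function(bins, centromere_bp) {
  bins <- as_tibble(bins)
  if (all(c("start_bp", "end_bp") %in% names(bins))) {
    mid <- (bins$start_bp + bins$end_bp) / 2
    bins$midpoint_dist_mb <- abs(mid - centromere_bp) / 1e6
  } else if (all(c("start_mb", "end_mb") %in% names(bins))) {
    mid <- (bins$start_mb + bins$end_mb) / 2
    bins$midpoint_dist_mb <- abs(mid - centromere_bp)
  } else {
    abort("bins need start/end coordinates")
  }
  bins
}

#' Gradient tests: density versus distance to the centromere
#'
#' Pearson correlation between per-bin density and midpoint distance to the
#' centromere, and a chi-square uniformity test of the counts with
#' length-proportional expected values.
#'
#' @param bin_stats A tibble with `n_loci`, `contig_length_mb`, `density`
#'   and `midpoint_dist_mb`.
#' @return A list with elements `pearson` ([pearson_test()]) and
#'   `uniformity` ([chisq_uniformity()]).
#' @export
gradient_tests <- function(bin_stats) {
  if (!"midpoint_dist_mb" %in% names(bin_stats) ||
      all(is.na(bin_stats$midpoint_dist_mb))) {
    abort("bin_stats needs midpoint_dist_mb (see centromere_distance)")
  }
  if (nrow(bin_stats) < 3) abort("need at least 3 bins")
  list(
    pearson = pearson_test(bin_stats$density, bin_stats$midpoint_dist_mb),
    uniformity = chisq_uniformity(bin_stats$n_loci, bin_stats$contig_length_mb)
  )
}

#' Detect gene islands on the physical map
#'
#' Builds a graph over loci with an edge whenever two loci share a BAC, sit
#' on overlapping BACs, or their BAC intervals lie on the same contig with
#' nearest edges separated by less than `gap_bp` (150 kb by default;
#' inter-contig gaps always break islands because the physical distance
#' across them is unknown). Islands are the connected components of size
#' two or more — a chain of pairwise-close loci is one island; all other
#' loci are isolated.
#'
#' @param loci A locus tibble (`locus_id`, `contig_id`, `start_bp`,
#'   `end_bp`).
#' @param map A [physical_map()] (unused beyond validation; distances come
#'   from the locus BAC intervals).
#' @param gap_bp Maximum separation between BAC-interval edges.
#' @return An `island_assignment`: the loci with `island_id` (`NA` when
#'   isolated) and `is_island` columns; the islands table (`island_id`,
#'   `n_loci`, `span_bp`) is in attribute `"islands"`.
#' @export
detect_islands <- function(loci, map, gap_bp = 150e3) {
  n <- nrow(loci)
  loci$island_id <- NA_character_
  loci$is_island <- FALSE
  if (n == 0) {
    attr(loci, "islands") <- tibble(island_id = character(), n_loci = integer(),
                                    span_bp = numeric())
    return(loci)
  }
  edges <- integer(0)
  placed <- which(!is.na(loci$contig_id) & !is.na(loci$start_bp))
  for (ctg in unique(loci$contig_id[placed])) {
    ix <- placed[loci$contig_id[placed] == ctg]
    if (length(ix) < 2) next
    ix <- ix[order(loci$start_bp[ix], loci$end_bp[ix])]
    # sorted sweep: same-BAC and overlapping-BAC loci have gap <= 0 anyway
    for (a in seq_len(length(ix) - 1)) {
      for (b in seq((a + 1), length(ix))) {
        gap <- loci$start_bp[ix[b]] - loci$end_bp[ix[a]]
        if (gap < gap_bp) edges <- c(edges, ix[a], ix[b]) else break
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  isl_comp <- unique(comp$membership[sizes >= 2])
  ids <- setNames(sprintf("isl_%04d", seq_along(isl_comp)), isl_comp)
  in_island <- sizes >= 2
  loci$is_island <- in_island
  loci$island_id[in_island] <- ids[as.character(comp$membership[in_island])]
  islands <- if (any(loci$is_island)) {
    loci %>%
      filter(.data$is_island) %>%
      group_by(.data$island_id) %>%
      summarise(n_loci = dplyr::n(),
                span_bp = max(.data$end_bp) - min(.data$start_bp),
                .groups = "drop")
  } else {
    tibble(island_id = character(), n_loci = integer(), span_bp = numeric())
  }
  attr(loci, "islands") <- islands
  class(loci) <- unique(c("island_assignment", class(loci)))
  loci
}

#' Per-bin island statistics
#'
#' @param loci An [detect_islands()] result with a `bin` column.
#' @param bin_lengths A data frame `bin`, `contig_length_mb`.
#' @return A `bin_stats` tibble with island/isolated counts, densities and
#'   `pct_island` per bin.
#' @export
island_bin_stats <- function(loci, bin_lengths) {
  binned <- loci %>% filter(!is.na(.data$bin))
  counts <- binned %>%
    group_by(.data$bin) %>%
    summarise(n_loci = dplyr::n(),
              n_island_loci = sum(.data$is_island),
              n_isolated_loci = sum(!.data$is_island),
              .groups = "drop")
  out <- as_tibble(bin_lengths) %>%
    left_join(counts, by = "bin") %>%
    mutate(
      across(c("n_loci", "n_island_loci", "n_isolated_loci"),
             ~ dplyr::coalesce(.x, 0L)),
      density = .data$n_loci / .data$contig_length_mb,
      island_density = .data$n_island_loci / .data$contig_length_mb,
      isolated_density = .data$n_isolated_loci / .data$contig_length_mb,
      pct_island = ifelse(.data$n_loci > 0, 100 * .data$n_island_loci / .data$n_loci,
                          NA_real_)
    )
  class(out) <- c("bin_stats", class(tibble()))
  out
}

#' Extrapolate gene counts to full bin sizes and a target total
#'
#' Step 1 projects the observed per-bin densities onto the full bin sizes
#' (`loci_i = density_i * full_size_i`); step 2 rescales all bins by a
#' common factor so the projected counts sum to `target_total`. The
#' kb-per-gene spacing is `1000 * full_size_mb / projected loci`.
#'
#' @param bin_stats A [bin_density()] result.
#' @param full_sizes A data frame `bin`, `full_size_mb`.
#' @param target_total Total locus count to rescale to (default: the
#'   projected total of step 1, i.e. no rescaling).
#' @return A tibble `bin`, `full_size_mb`, `projected_loci`,
#'   `projected_loci_scaled`, `kb_per_gene`.
#' @export
extrapolate_density <- function(bin_stats, full_sizes, target_total = NULL) {
  full_sizes <- as_tibble(full_sizes)
  if (!all(bin_stats$bin %in% full_sizes$bin)) {
    warn("full bin sizes missing; extrapolation skipped")
    return(NULL)
  }
  out <- left_join(as_tibble(bin_stats)[, c("bin", "density")], full_sizes, by = "bin") %>%
    mutate(projected_loci = .data$density * .data$full_size_mb)
  total <- sum(out$projected_loci)
  target_total <- target_total %||% total
  out <- out %>%
    mutate(projected_loci_scaled = .data$projected_loci * target_total / total,
           kb_per_gene = 1000 * .data$full_size_mb / .data$projected_loci_scaled)
  out
}

#' Fraction of genes missed relative to a reference density profile
#'
#' Compares this experiment's normalised densities with a reference profile
#' (e.g. from an independent mapping experiment) on the same bins:
#' `missed_i = 1 - normalized_observed_i / normalized_reference_i`, floored
#' at 0. A deficit relative to the reference is read as genes the
#' presence/absence assay cannot see, e.g. tandemly duplicated copies.
#'
#' @param normalized_observed,normalized_reference Numeric vectors on the
#'   same bins.
#' @return Numeric vector of missed fractions (`NA` where the reference is
#'   0).
#' @export
tandem_correction <- function(normalized_observed, normalized_reference) {
  if (length(normalized_observed) != length(normalized_reference)) {
    abort("profiles must cover the same bins")
  }
  out <- 1 - normalized_observed / normalized_reference
  out[normalized_reference == 0] <- NA_real_
  pmax(out, 0)
}

#' Bundled deletion-bin mapping table for wheat chromosome 3B
#'
#' Example dataset: per-deletion-bin cumulative contig lengths, mapped locus
#' counts, and cross-species mapping/collinearity counts against barley
#' chromosome 3H and rice chromosome 1 for wheat chromosome 3B, as used in
#' the worked examples. Bin rows are ordered from the short-arm telomere to
#' the long-arm telomere; the `total_assigned`, `not_assigned` and `total`
#' rows are excluded (recompute them with [bin_density()] etc.).
#'
#' @param path Optional path to an alternative table with the same columns.
#' @return A tibble with columns `bin`, `contig_length_mb`, `n_loci`,
#'   `barley_3h`, `barley_other`, `collinear_3h`, `rice_1`, `rice_other`,
#'   `collinear_rice_1`.
#' @export
wheat3b_bin_table <- function(path = system.file("extdata", "wheat3b_bins.tsv",
                                                 package = "poolanchor")) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Bundled whole-chromosome mapping summary for wheat chromosome 3B
#'
#' Example dataset: whole-chromosome companion to [wheat3b_bin_table()] —
#' probe and locus totals from the pooled-hybridisation screen, counts of
#' loci mapped to barley chromosome 3H / rice chromosome 1 versus other
#' chromosomes, collinear counts, and the array/genome constants used in
#' the expected-probe calculation.
#'
#' @param path Optional path to an alternative table.
#' @return A named numeric vector.
#' @export
wheat3b_summary <- function(path = system.file("extdata", "wheat3b_summary.tsv",
                                               package = "poolanchor")) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  setNames(df$value, df$quantity)
}
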