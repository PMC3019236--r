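#' Attach genetic-map positions to loci through marker alignments
#'
#' Links probes to genetically mapped markers: among the candidate
#' alignments of each probe, the best hit passing the link rule (at least
#' `min_identity` percent identity over `min_length` aligned nucleotides,
#' 85%/100 nt by default) is attached; probes with no passing hit stay
#' unmapped.
#'
#' @param loci A locus tibble with `probe_id`.
#' @param gmap Genetic map: data frame `marker_id`, `chromosome`,
#'   `position_cm`.
#' @param hits Candidate alignments: data frame `probe_id`, `marker_id`,
#'   `identity_pct`, `length_nt`.
#' @param min_identity,min_length The link rule.
#' @return `loci` with `ref_chr` and `ref_pos` columns (`NA` when unmapped).
#' @export
attach_map_positions <- function(loci, gmap, hits, min_identity = 85,
                                 min_length = 100) {
  hits <- as_tibble(hits) %>%
    filter(.data$identity_pct >= min_identity, .data$length_nt >= min_length) %>%
    arrange(dplyr::desc(.data$identity_pct), dplyr::desc(.data$length_nt)) %>%
    distinct(.data$probe_id, .keep_all = TRUE)
  gmap <- as_tibble(gmap)
  hits <- left_join(hits, gmap, by = "marker_id")
  loci$ref_chr <- hits$chromosome[match(loci$probe_id, hits$probe_id)]
  loci$ref_pos <- hits$position_cm[match(loci$probe_id, hits$probe_id)]
  loci
}

#' Synteny summary against a reference chromosome
#'
#' A locus is syntenic when it maps to the orthologous reference chromosome,
#' irrespective of order. Summarised overall and per deletion bin.
#'
#' @param loci A locus tibble with `ref_chr` and (optionally) `bin`.
#' @param ortholog_chr The orthologous chromosome label.
#' @return A `synteny_summary` object with `overall` and `per_bin` tibbles;
#'   see [tidy()] and [glance()] methods.
#' @export
synteny_summary <- function(loci, ortholog_chr) {
  mapped <- loci[!is.na(loci$ref_chr), , drop = FALSE]
  syn <- mapped$ref_chr == ortholog_chr
  overall <- tibble(
    reference = ortholog_chr,
    n_mapped = nrow(mapped),
    n_syntenic = sum(syn),
    n_nonsyntenic = sum(!syn),
    pct_syntenic = if (nrow(mapped) > 0) 100 * sum(syn) / nrow(mapped) else NA_real_
  )
  per_bin <- NULL
  if ("bin" %in% names(mapped)) {
    per_bin <- mapped %>%
      filter(!is.na(.data$bin)) %>%
      group_by(.data$bin) %>%
      summarise(
        n_syntenic = sum(.data$ref_chr == ortholog_chr),
        n_other = sum(.data$ref_chr != ortholog_chr),
        pct_syntenic = 100 * .data$n_syntenic / (.data$n_syntenic + .data$n_other),
        .groups = "drop"
      )
  }
  structure(list(overall = overall, per_bin = per_bin, reference = ortholog_chr),
            class = "synteny_summary")
}

#' @export
print.synteny_summary <- function(x, ...) {
  cat("Synteny vs ", x$reference, ": ", x$overall$n_syntenic, "/",
      x$overall$n_mapped, " (", round(x$overall$pct_syntenic), "%)\n", sep = "")
  invisible(x)
}

#' Test for mapping bias of non-syntenic loci across chromosomes
#'
#' Chi-square of the observed non-syntenic counts against expectations
#' proportional to each chromosome's gene total, plus the Pearson
#' correlation between counts and totals. Chromosomes with a zero expected
#' count are pooled into an `"other"` category with a warning.
#'
#' @param counts Named vector of non-syntenic locus counts per chromosome.
#' @param totals Named vector of gene totals per chromosome (same names).
#' @return A `bias_tests` object; see [glance()].
#' @export
bias_tests <- function(counts, totals) {
  if (length(counts) < 2) abort("need counts on at least 2 chromosomes")
  if (!is.null(names(counts)) && !is.null(names(totals))) {
    totals <- totals[names(counts)]
  }
  zero <- totals == 0
  if (any(zero)) {
    warn(paste0("chromosome(s) with zero expected count pooled into 'other': ",
                paste(names(counts)[zero], collapse = ", ")))
    counts <- c(counts[!zero], other = sum(counts[zero]))
    totals <- c(totals[!zero], other = 0)
    totals["other"] <- max(totals["other"], 1e-9)
  }
  expected <- sum(counts) * totals / sum(totals)
  stat <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1
  p_chi <- pchisq(stat, df, lower.tail = FALSE)
  if (length(counts) >= 3) {
    ct <- suppressWarnings(cor.test(as.numeric(counts), as.numeric(totals)))
    r <- unname(ct$estimate)
    p_r <- ct$p.value
  } else { # correlation is degenerate on two points; no p-value
    r <- suppressWarnings(cor(as.numeric(counts), as.numeric(totals)))
    p_r <- NA_real_
  }
  structure(
    list(chisq = list(statistic = stat, df = df, p_value = p_chi, expected = expected),
         pearson = list(r = r, p_value = p_r, n = length(counts))),
    class = "bias_tests"
  )
}

#' Chi-square uniformity test with constructed expected values
#'
#' Tests whether observed per-bin counts are uniform relative to per-bin
#' totals: the global proportion `sum(observed) / sum(totals)` is applied to
#' each bin's total to build the theoretical values, and a Pearson
#' chi-square with `bins - 1` degrees of freedom is computed. For density
#' uniformity the totals are the bins' cumulative contig lengths, so the
#' expected counts are proportional to length.
#'
#' @param observed Per-bin observed counts.
#' @param totals Per-bin totals (counts or lengths), all positive.
#' @return A `uniformity_test` object; see [tidy()] and [glance()].
#' @export
chisq_uniformity <- function(observed, totals) {
  if (length(observed) < 2) abort("need at least 2 bins")
  if (length(observed) != length(totals)) abort("observed and totals differ in length")
  if (any(totals <= 0)) abort("totals must be positive")
  pbar <- sum(observed) / sum(totals)
  expected <- pbar * totals
  if (any(expected < 1)) {
    warn("expected count below 1 in at least one bin; chi-square approximation is weak")
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  structure(
    list(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         proportion = pbar, observed = observed, expected = expected),
    class = "uniformity_test"
  )
}

#' Pearson correlation test
#'
#' Sample correlation with a two-sided p-value from the t transform on
#' `n - 2` degrees of freedom (delegated to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, length >= 3, neither constant.
#' @return A `pearson_test` object; see [glance()].
#' @export
pearson_test <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 df = unname(ct$parameter), n = length(x)),
            class = "pearson_test")
}

#' Two-sample Welch t-test
#'
#' Two-sided, unequal variances (delegated to [stats::t.test()]).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `welch_t_test` object; see [glance()].
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) abort("zero variance in both groups")
  tt <- t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b)),
            class = "welch_t_test")
}

#' Build synteny blocks on a reference from binned loci
#'
#' The relative order of loci within a deletion bin is unknown, so a virtual
#' order is inferred from the reference: loci are sorted by bin (in bin
#' order), and the largest subset whose reference positions are
#' non-decreasing (longest increasing subsequence) defines the consistent
#' assignment; loci falling outside it are excluded from block construction
#' and typically classified non-collinear downstream. Each bin's block is
#' the [min, max] interval of its kept loci on the reference.
#'
#' @param loci A locus tibble with `bin` and `ref_pos` (syntenic, binned
#'   loci).
#' @param bin_order Character vector giving the bins in chromosome order.
#' @return A tibble of blocks: `bin`, `ref_min`, `ref_max`, `n_loci` (kept);
#'   empty bins yield `NA` intervals. Kept locus ids are in attribute
#'   `"kept"`.
#' @export
build_synteny_blocks <- function(loci, bin_order) {
  loci <- loci[!is.na(loci$bin) & !is.na(loci$ref_pos), , drop = FALSE]
  loci <- loci[order(match(loci$bin, bin_order), loci$ref_pos), , drop = FALSE]
  keep <- longest_nondecreasing(loci$ref_pos)
  kept <- loci[keep, , drop = FALSE]
  blocks <- tibble(bin = bin_order) %>%
    left_join(
      kept %>% group_by(.data$bin) %>%
        summarise(ref_min = min(.data$ref_pos), ref_max = max(.data$ref_pos),
                  n_loci = dplyr::n(), .groups = "drop"),
      by = "bin"
    )
  blocks$n_loci[is.na(blocks$n_loci)] <- 0L
  attr(blocks, "kept") <- if ("locus_id" %in% names(kept)) kept$locus_id else which(keep)
  blocks
}

# Indices of a longest non-decreasing subsequence (O(n^2) DP; earliest
# optimum on ties).
longest_nondecreasing <- function(x) {
  n <- length(x)
  if (n == 0) return(logical(0))
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(len)
  keep <- logical(n)
  while (end != 0L) {
    keep[end] <- TRUE
    end <- prev[end]
  }
  keep
}

#' Collinearity summary against synteny blocks
#'
#' A binned syntenic locus is collinear when its reference position falls
#' inside its own bin's synteny block (inclusive interval).
#'
#' @param loci A locus tibble with `bin` and `ref_pos`.
#' @param blocks Blocks from [build_synteny_blocks()].
#' @return A `collinearity_summary` object with `per_bin` and `overall`
#'   tibbles; see [tidy()] and [glance()].
#' @export
collinearity_summary <- function(loci, blocks) {
  loci <- loci[!is.na(loci$bin) & !is.na(loci$ref_pos), , drop = FALSE]
  bi <- match(loci$bin, blocks$bin)
  coll <- !is.na(blocks$ref_min[bi]) &
    loci$ref_pos >= blocks$ref_min[bi] & loci$ref_pos <= blocks$ref_max[bi]
  per_bin <- tibble(bin = loci$bin, collinear = coll) %>%
    group_by(.data$bin) %>%
    summarise(n_loci = dplyr::n(), n_collinear = sum(.data$collinear),
              pct_collinear = 100 * .data$n_collinear / .data$n_loci,
              .groups = "drop")
  overall <- tibble(
    n_loci = nrow(loci), n_collinear = sum(coll),
    pct_collinear = if (nrow(loci) > 0) 100 * sum(coll) / nrow(loci) else NA_real_
  )
  structure(list(per_bin = per_bin, overall = overall, collinear = coll),
            class = "collinearity_summary")
}
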