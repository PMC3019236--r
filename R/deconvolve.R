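#' Deconvolve positive pools into BAC addresses
#'
#' Turns the per-probe positive pools of a scoring result into BAC addresses
#' using the physical map. A probe with one positive pool per axis implies a
#' single well, accepted when an MTP BAC sits there. For probes with several
#' positives on one or more axes, every well combination of the positive
#' coordinates is enumerated and the probe is resolved when the existing
#' BACs among them form a unique minimal set of one to three mutually
#' overlapping BACs that explains every positive pool (a gene sitting on the
#' overlap itself); when both a single well and a larger combination are
#' consistent, the smaller address set wins. Anything else is left
#' unresolved with a reason.
#'
#' @param scores A `pool_scores` tibble ([score_automated()] etc.).
#' @param layout A [pool_layout()].
#' @param map A [physical_map()].
#' @param max_bacs Largest address set considered (default 3).
#' @param max_combinations Guard against pathological probes (e.g. repeats)
#'   whose positives imply too many wells; such probes are left unresolved.
#' @return A tibble of addresses (`probe_id`, `bac_id`, `plate`, `row`,
#'   `column`, `method`, `resolution`), with the unresolved probes and their
#'   reasons in attribute `"unresolved"`.
#' @export
resolve_addresses <- function(scores, layout, map, max_bacs = 3,
                              max_combinations = 2000) {
  byp <- positives_by_probe(scores)
  method <- attr(scores, "method") %||% "automated"
  out <- list()
  unresolved <- list()
  give_up <- function(probe, reason) {
    unresolved[[length(unresolved) + 1]] <<- tibble(probe_id = probe, reason = reason)
  }
  for (i in seq_len(nrow(byp))) {
    probe <- byp$probe_id[i]
    sets <- list(plate = byp$plate[[i]], row = byp$row[[i]], column = byp$column[[i]])
    if (any(lengths(sets) == 0)) {
      give_up(probe, "missing_axis")
      next
    }
    if (prod(lengths(sets)) > max_combinations) {
      give_up(probe, "too_many_positive_pools")
      next
    }
    sol <- solve_combination(map, sets, max_bacs = max_bacs)
    if (is.character(sol)) {
      give_up(probe, sol)
      next
    }
    sol$probe_id <- probe
    sol$method <- method
    out[[length(out) + 1]] <- sol
  }
  addresses <- finalize_addresses(out)
  attr(addresses, "unresolved") <- if (length(unresolved) > 0) bind_rows(unresolved) else
    tibble(probe_id = character(), reason = character())
  addresses
}

# Find the unique minimal set (1..max_bacs) of existing, mutually overlapping
# BACs whose well coordinates exactly reproduce the positive pools. Returns a
# tibble of wells, or a character reason when unresolved.
solve_combination <- function(map, sets, max_bacs = 3) {
  wells <- enumerate_wells(map, sets$plate, sets$row, sets$column)
  exist <- wells[!is.na(wells$bac_id), , drop = FALSE]
  if (nrow(exist) == 0) return("no_bac_at_any_well")
  want <- list(plate = sort(as.integer(sub("^P", "", sets$plate))),
               row = sort(sub("^R", "", sets$row)),
               column = sort(as.integer(sub("^C", "", sets$column))))
  for (size in seq_len(min(max_bacs, nrow(exist)))) {
    subsets <- combn(seq_len(nrow(exist)), size, simplify = FALSE)
    hits <- keep(subsets, function(ix) {
      sub <- exist[ix, , drop = FALSE]
      identical(sort(unique(sub$plate)), want$plate) &&
        identical(sort(unique(sub$row)), want$row) &&
        identical(sort(unique(sub$column)), want$column) &&
        bacs_mutually_overlap(map, sub$bac_id)
    })
    if (length(hits) == 1) {
      sol <- exist[hits[[1]], , drop = FALSE]
      sol$resolution <- c("unique", "overlapping_pair", "overlapping_triple")[size]
      return(sol)
    }
    if (length(hits) > 1) return("ambiguous")
  }
  "no_consistent_combination"
}

#' Merge BAC addresses into gene loci
#'
#' Addresses of one probe that sit on mutually overlapping BACs merge into a
#' single locus (the gene lies on the overlap); disjoint placements of the
#' same probe become separate loci flagged as duplicated. Each locus carries
#' its contig and the physical interval spanned by its BACs.
#'
#' @param addresses An address tibble ([resolve_addresses()] and friends).
#' @param map A [physical_map()].
#' @return A tibble of loci: `locus_id`, `probe_id`, `bac_ids` (list),
#'   `n_bacs`, `contig_id`, `start_bp`, `end_bp`, `method`, `duplicated`.
#'   Summary counts are kept in attribute `"counts"`.
#' @export
build_loci <- function(addresses, map) {
  if (nrow(addresses) == 0) {
    out <- tibble(locus_id = character(), probe_id = character(), bac_ids = list(),
                  n_bacs = integer(), contig_id = character(), start_bp = numeric(),
                  end_bp = numeric(), method = character(), duplicated = logical())
    attr(out, "counts") <- tibble(n_probes = 0L, n_addresses = 0L, n_loci = 0L,
                                  n_duplicated = 0L)
    return(out)
  }
  bac_tab <- map$bacs
  out <- list()
  for (probe in unique(addresses$probe_id)) {
    rows <- addresses[addresses$probe_id == probe, , drop = FALSE]
    ids <- unique(rows$bac_id)
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    igraph::V(g)$name <- ids
    if (length(ids) > 1) {
      prs <- combn(ids, 2)
      ov <- bacs_overlap(map, prs[1, ], prs[2, ])
      if (any(ov)) g <- igraph::add_edges(g, as.vector(prs[, ov, drop = FALSE]))
    }
    comp <- igraph::components(g)$membership
    n_comp <- max(comp)
    for (k in seq_len(n_comp)) {
      members <- ids[comp == k]
      info <- bac_tab[match(members, bac_tab$bac_id), , drop = FALSE]
      out[[length(out) + 1]] <- tibble(
        locus_id = if (n_comp == 1) probe else paste0(probe, "/", k),
        probe_id = probe,
        bac_ids = list(sort(members)),
        n_bacs = length(members),
        contig_id = info$contig_id[1],
        start_bp = suppressWarnings(min(info$start_bp)),
        end_bp = suppressWarnings(max(info$end_bp)),
        method = rows$method[match(members[1], rows$bac_id)],
        duplicated = n_comp > 1
      )
    }
  }
  loci <- bind_rows(out)
  attr(loci, "counts") <- tibble(
    n_probes = length(unique(addresses$probe_id)),
    n_addresses = nrow(distinct(addresses, .data$probe_id, .data$bac_id)),
    n_loci = nrow(loci),
    n_duplicated = sum(loci$duplicated)
  )
  loci
}

#' Assign loci to deletion bins through their contigs
#'
#' A locus inherits the deletion bin of its contig; loci on unbinned contigs
#' (including singletons) get `NA`. A locus whose BACs disagree on the bin
#' breaks a map invariant and raises an error.
#'
#' @param loci A locus tibble ([build_loci()]).
#' @param map A [physical_map()].
#' @return `loci` with a `bin` column; the assigned / not-assigned split is
#'   kept in attribute `"summary"`.
#' @export
assign_bins <- function(loci, map) {
  bac_bins <- setNames(map$bacs$bin, map$bacs$bac_id)
  bins <- map_chr(loci$bac_ids, function(ids) {
    bs <- unique(bac_bins[ids])
    if (length(bs) > 1) {
      abort(paste0("conflicting bins within one locus (BACs ",
                   paste(ids, collapse = ", "), ")"))
    }
    bs
  })
  loci$bin <- unname(bins)
  attr(loci, "summary") <- tibble(
    assigned = sum(!is.na(loci$bin)),
    not_assigned = sum(is.na(loci$bin))
  )
  loci
}

#' Confirm hybridisation placements against annotated contigs
#'
#' Given an annotation of a subset of contigs (e.g. sequenced contigs where
#' probe alignments are known), reports what fraction of the loci placed on
#' those contigs by hybridisation have an annotation hit, and of those, what
#' fraction lie at the expected location.
#'
#' @param loci A locus tibble with `contig_id`.
#' @param annotation A data frame with columns `probe_id`, `contig_id` and
#'   logical `expected` (hit at the expected location); one row per hit.
#' @param annotated_contigs Contigs covered by the annotation (defaults to
#'   those present in `annotation`).
#' @return A one-row tibble: `n_placed`, `n_hit`, `pct_hit`,
#'   `n_at_expected`, `pct_at_expected`. Fractions are `NA` when undefined.
#' @export
validate_against_annotation <- function(loci, annotation,
                                        annotated_contigs = unique(annotation$contig_id)) {
  annotation <- as_tibble(annotation)
  placed <- loci[loci$contig_id %in% annotated_contigs, , drop = FALSE]
  n_placed <- nrow(placed)
  key <- paste(annotation$probe_id, annotation$contig_id)
  has_hit <- paste(placed$probe_id, placed$contig_id) %in% key
  n_hit <- sum(has_hit)
  hit_rows <- annotation[match(paste(placed$probe_id, placed$contig_id)[has_hit], key), ]
  n_expected <- sum(hit_rows$expected)
  tibble(
    n_placed = n_placed,
    n_hit = n_hit,
    pct_hit = if (n_placed > 0) 100 * n_hit / n_placed else NA_real_,
    n_at_expected = n_expected,
    pct_at_expected = if (n_hit > 0) 100 * n_expected / n_hit else NA_real_
  )
}
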