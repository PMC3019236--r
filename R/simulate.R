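#' Configuration for a synthetic pooled-hybridisation experiment
#'
#' Bundles all parameters of the generator: chromosome and minimal tiling
#' path geometry, pool design, gene-space structure (density gradient,
#' islands), probe-target divergence and its effect on signal, per-BAC
#' abundance heterogeneity, background noise and repeat probes. Defaults
#' reproduce the structure of a study-scale screen: a ~1 Gb chromosome whose
#' MTP covers 82% with ~30% BAC overlap, pooled in three dimensions
#' (20 plate, 16 row, 24 column pools), a twofold centromere-to-telomere
#' gene-density gradient, distally enriched gene islands, and hybridisation
#' signal attenuated by 73-99% at 90% probe-target identity with total loss
#' below 80% identity.
#'
#' @param chromosome_length_bp Chromosome length.
#' @param centromere_fraction Centromere position as a fraction of length.
#' @param n_plates,n_rows,n_cols Pool geometry; capacity must hold the MTP.
#' @param bac_length_mean_bp,bac_length_jitter BAC insert length mean and
#'   coefficient of variation.
#' @param mtp_overlap_fraction Pairwise overlap between adjacent MTP BACs.
#' @param mtp_coverage_fraction Fraction of the chromosome covered by
#'   contigs; the rest is inter-contig gap.
#' @param n_contigs Number of contigs the covered fraction is split into.
#' @param unbinned_contig_fraction Fraction of contigs left without a
#'   deletion-bin assignment.
#' @param n_genes Number of gene probes placed.
#' @param density_gradient_ratio Telomere / centromere gene density ratio
#'   (>= 1; 1 = uniform).
#' @param island_fraction_distal,island_fraction_proximal Probability that a
#'   gene is an island member at the telomere / at the centromere (linear in
#'   between).
#' @param island_gap_bp Intra-island gene spacing scale (< 150 kb).
#' @param isolation_bp Minimum clearance kept around isolated genes and
#'   island clusters so that distinct placements do not merge into chance
#'   islands at the 150 kb detection gap.
#' @param duplication_prob Probability that a probe receives a second,
#'   disjoint placement (a duplicated locus).
#' @param identity_distribution Probe-target identity model: a list with
#'   `mean`, `sd`, `min`, `max` (truncated normal, percent identity).
#' @param attenuation_range Range the fractional signal decrease at 90%
#'   identity is drawn from.
#' @param floor_identity Identity at and below which the signal is fully
#'   attenuated (the detectability floor).
#' @param bac_abundance_cv Coefficient of variation of per-BAC abundance
#'   within a pool (log-normal, mean 1); pools of hundreds of BACs cannot be
#'   kept equimolar.
#' @param background Background intensity model: list with `meanlog`,
#'   `sdlog`, `scale` (log-normal; `scale = 0` gives a noiseless matrix).
#' @param base_signal Signal of a fully identical, unit-abundance target.
#' @param n_te_probes Number of repeat-derived probes injected.
#' @param te_pool_fraction Fraction of pools a repeat probe lights up.
#' @param seed Random seed used by [simulate_experiment()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(chromosome_length_bp = 995e6,
                       centromere_fraction = 0.4,
                       n_plates = 20, n_rows = 16, n_cols = 24,
                       bac_length_mean_bp = 157e3,
                       bac_length_jitter = 0.08,
                       mtp_overlap_fraction = 0.30,
                       mtp_coverage_fraction = 0.82,
                       n_contigs = 200,
                       unbinned_contig_fraction = 0.1,
                       n_genes = 800,
                       density_gradient_ratio = 2.0,
                       island_fraction_distal = 0.5,
                       island_fraction_proximal = 0.25,
                       island_gap_bp = 1e5,
                       isolation_bp = 150e3 + 2.5 * bac_length_mean_bp,
                       duplication_prob = 0.02,
                       identity_distribution = list(mean = 88, sd = 5, min = 75, max = 100),
                       attenuation_range = c(0.73, 0.99),
                       floor_identity = 80,
                       bac_abundance_cv = 0.3,
                       background = list(meanlog = 0, sdlog = 0.25, scale = 1),
                       base_signal = 100,
                       n_te_probes = 5,
                       te_pool_fraction = 0.4,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(mtp_overlap_fraction, mtp_coverage_fraction, unbinned_contig_fraction,
             island_fraction_distal, island_fraction_proximal, centromere_fraction,
             duplication_prob, te_pool_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (density_gradient_ratio < 1) abort("density_gradient_ratio must be >= 1")
  if (island_gap_bp >= 150e3 + 1) warn("island_gap_bp is meant to be < 150 kb")
  structure(cfg, class = "sim_config")
}

#' Simulate a physical map with a minimal tiling path and 3-D pools
#'
#' Splits the covered fraction of the chromosome into contigs separated by
#' gaps, tiles each contig with BACs at the configured pairwise overlap,
#' assigns BACs to wells plate by plate along the map, and lays eight
#' deletion bins over the chromosome (three short-arm, two centromeric, three
#' long-arm), assigning each contig to the bin holding its midpoint.
#'
#' @param cfg A [sim_config()].
#' @return A [physical_map()].
#' @export
simulate_physical_map <- function(cfg) {
  len <- cfg$chromosome_length_bp
  covered <- cfg$mtp_coverage_fraction * len
  n_ctg <- cfg$n_contigs
  L <- cfg$bac_length_mean_bp

  w <- rexp(n_ctg)
  ctg_len <- pmax(covered * w / sum(w), 3 * L)
  ctg_len <- ctg_len * covered / sum(ctg_len)
  gap_total <- len - covered
  if (gap_total > 0) {
    gw <- rexp(n_ctg + 1)
    gaps <- gap_total * gw / sum(gw)
  } else {
    gaps <- rep(0, n_ctg + 1)
  }
  starts <- cumsum(gaps[seq_len(n_ctg)]) + cumsum(c(0, ctg_len[-n_ctg]))
  ends <- starts + ctg_len

  bac_rows <- vector("list", n_ctg)
  for (ci in seq_len(n_ctg)) {
    cs <- starts[ci]
    ce <- ends[ci]
    bs <- numeric(0)
    be <- numeric(0)
    pos <- cs
    repeat {
      li <- draw_bac_length(L, cfg$bac_length_jitter)
      if (pos + li >= ce) {
        if (length(bs) > 0 && (ce - pos) < 0.4 * L) {
          be[length(be)] <- ce # extend the previous BAC instead of a sliver
        } else {
          bs <- c(bs, pos)
          be <- c(be, ce)
        }
        break
      }
      bs <- c(bs, pos)
      be <- c(be, pos + li)
      pos <- pos + li * (1 - cfg$mtp_overlap_fraction)
    }
    bac_rows[[ci]] <- tibble(contig_id = sprintf("ctg%04d", ci),
                             start_bp = bs, end_bp = be)
  }
  bacs <- bind_rows(bac_rows)
  n_bacs <- nrow(bacs)
  capacity <- cfg$n_plates * cfg$n_rows * cfg$n_cols
  if (n_bacs > capacity) {
    abort(paste0("pool geometry capacity (", capacity, " wells) exceeded by ",
                 n_bacs, " MTP BACs"))
  }
  idx <- seq_len(n_bacs) - 1L
  per_plate <- cfg$n_rows * cfg$n_cols
  bacs$bac_id <- sprintf("bac%05d", seq_len(n_bacs))
  bacs$plate <- idx %/% per_plate + 1L
  rem <- idx %% per_plate
  bacs$row <- LETTERS[rem %/% cfg$n_cols + 1L]
  bacs$column <- rem %% cfg$n_cols + 1L

  bins <- make_bins(len, cfg$centromere_fraction)
  mid <- (starts + ends) / 2
  ctg_bin <- bins$bin[findInterval(mid, bins$start_bp)]
  if (cfg$unbinned_contig_fraction > 0) {
    drop <- sample(n_ctg, round(cfg$unbinned_contig_fraction * n_ctg))
    ctg_bin[drop] <- NA_character_
  }
  bacs$bin <- ctg_bin[match(bacs$contig_id, sprintf("ctg%04d", seq_len(n_ctg)))]

  physical_map(bacs, bins = bins)
}

draw_bac_length <- function(mean_bp, jitter) {
  if (jitter <= 0) return(mean_bp)
  max(0.5 * mean_bp, min(1.5 * mean_bp, rnorm(1, mean_bp, jitter * mean_bp)))
}

# Eight deletion bins: telomere(S) -> centromere -> telomere(L), using
# fraction-of-arm breakpoints, with the two centromere-flanking bins tagged C.
make_bins <- function(len, centromere_fraction) {
  C <- centromere_fraction * len
  LL <- len - C
  s_breaks <- C * (1 - c(1.00, 0.78, 0.57, 0.33, 0))
  l_breaks <- C + LL * c(0, 0.22, 0.50, 0.63, 1.00)
  tibble(
    bin = c("S-0.78-1.00", "S-0.57-0.78", "S-0.33-0.57", "C-S-0.33",
            "C-L-0.22", "L-0.22-0.50", "L-0.50-0.63", "L-0.63-1.00"),
    arm = c("S", "S", "S", "C", "C", "L", "L", "L"),
    start_bp = c(s_breaks[1:4], l_breaks[1:4]),
    end_bp = c(s_breaks[2:5], l_breaks[2:5])
  )
}

#' Place genes on the simulated chromosome
#'
#' Gene positions are drawn from a piecewise-linear density rising from the
#' centromere towards each telomere by `density_gradient_ratio`. A
#' distance-dependent fraction of genes is laid down as island clusters
#' (2-4 genes with intra-cluster spacing below `island_gap_bp`); the
#' remaining genes are kept isolated, with at least `isolation_bp` clearance
#' so they cannot merge into chance islands. Each probe draws a target
#' identity from the configured distribution; a small fraction of probes
#' receives a second disjoint placement (duplicated locus). Ground-truth
#' island membership is recomputed from the realised BAC footprints by a
#' positional sweep, independently of the graph-based island detector.
#'
#' @param cfg A [sim_config()].
#' @param map A [physical_map()] from [simulate_physical_map()].
#' @return A `truth_set` tibble with one row per placement: `probe_id`,
#'   `position_bp`, `contig_id`, `bac_ids` (list), `n_bacs`, `in_gap`,
#'   `identity`, `requested_island`, `is_island`, `island_id`, `duplicated`,
#'   `expected_pools` (list).
#' @export
place_genes <- function(cfg, map) {
  len <- cfg$chromosome_length_bp
  C <- cfg$centromere_fraction * len
  r <- cfg$density_gradient_ratio
  dist01 <- function(x) ifelse(x < C, (C - x) / C, (x - C) / (len - C))
  draw_pos <- function() {
    repeat {
      x <- runif(1, 0, len)
      if (runif(1) < (1 + (r - 1) * dist01(x)) / r) return(x)
    }
  }

  p_island <- function(x) cfg$island_fraction_proximal +
    (cfg$island_fraction_distal - cfg$island_fraction_proximal) * dist01(x)

  # Decide island membership gene by gene at gradient-weighted positions,
  # so the realised island fraction is binomial around the requested curve.
  flags <- map_lgl(seq_len(cfg$n_genes), function(i) runif(1) < p_island(draw_pos()))
  n_island <- sum(flags)
  sizes <- integer(0)
  left <- n_island
  while (left > 0) {
    s <- sample(2:4, 1, prob = c(0.5, 0.3, 0.2))
    if (left - s == 1) s <- s + 1
    s <- min(s, left)
    if (s == 1) { # a single leftover joins the previous cluster
      sizes[length(sizes)] <- sizes[length(sizes)] + 1
      left <- 0
    } else {
      sizes <- c(sizes, s)
      left <- left - s
    }
  }

  ctg <- map$contigs[!grepl("^singleton:", map$contigs$contig_id), , drop = FALSE]
  ctg <- ctg[order(ctg$start_bp), , drop = FALSE]
  contig_at <- function(x) {
    i <- findInterval(x, ctg$start_bp)
    if (i >= 1 && x < ctg$end_bp[i]) i else NA_integer_
  }

  occupied <- numeric(0)
  clear_of <- function(from, to) {
    length(occupied) == 0 || !any(occupied > from & occupied < to)
  }
  place_with_clearance <- function(span, tries = 500) {
    for (t in seq_len(tries)) {
      x <- draw_pos()
      if (x + span > len) next
      if (!clear_of(x - cfg$isolation_bp, x + span + cfg$isolation_bp)) next
      if (span > 0) {
        ci <- contig_at(x)
        if (!is.na(ci) && x + span > ctg$end_bp[ci]) next # cluster must fit its contig
      }
      return(x)
    }
    draw_pos() # best effort after exhausting tries
  }

  positions <- numeric(0)
  island_requested <- logical(0)
  for (s in sizes) {
    gaps <- runif(s - 1, 0.2, 0.9) * cfg$island_gap_bp
    anchor <- place_with_clearance(sum(gaps))
    member_pos <- anchor + cumsum(c(0, gaps))
    positions <- c(positions, member_pos)
    island_requested <- c(island_requested, rep(TRUE, s))
    occupied <- sort(c(occupied, member_pos))
  }
  for (i in seq_len(cfg$n_genes - n_island)) {
    x <- place_with_clearance(0)
    positions <- c(positions, x)
    island_requested <- c(island_requested, FALSE)
    occupied <- sort(c(occupied, x))
  }

  ord <- sample(seq_along(positions)) # decouple probe ids from placement order
  positions <- positions[ord]
  island_requested <- island_requested[ord]
  probe_id <- sprintf("probe_%04d", seq_along(positions))
  identity <- draw_identity(length(positions), cfg$identity_distribution)

  truth <- tibble(probe_id = probe_id, position_bp = positions,
                  identity = identity, requested_island = island_requested,
                  duplicated = FALSE)

  # Duplicated loci: same probe, second disjoint placement.
  dup <- which(runif(nrow(truth)) < cfg$duplication_prob)
  if (length(dup) > 0) {
    extra <- truth[dup, , drop = FALSE]
    extra$position_bp <- map_dbl(dup, function(i) place_with_clearance(0))
    extra$requested_island <- FALSE
    truth$duplicated[dup] <- TRUE
    extra$duplicated <- TRUE
    truth <- bind_rows(truth, extra)
  }

  truth <- annotate_placements(truth, map)
  truth <- realized_islands(truth, map, gap_bp = 150e3)
  class(truth) <- c("truth_set", class(truth))
  attr(truth, "cfg") <- cfg
  truth
}

draw_identity <- function(n, dist) {
  x <- rnorm(n, dist$mean, dist$sd)
  pmin(dist$max, pmax(dist$min, x))
}

# Covering BACs, contig and expected positive pools for each placement.
annotate_placements <- function(truth, map) {
  bacs <- map$bacs
  cover <- map(truth$position_bp, function(x) {
    hit <- bacs$bac_id[!is.na(bacs$start_bp) & bacs$start_bp <= x & x < bacs$end_bp]
    sort(hit)
  })
  truth$bac_ids <- cover
  truth$n_bacs <- lengths(cover)
  truth$in_gap <- truth$n_bacs == 0
  truth$contig_id <- map_chr(cover, function(ids) {
    if (length(ids) == 0) NA_character_ else
      bacs$contig_id[match(ids[1], bacs$bac_id)]
  })
  truth$expected_pools <- map(cover, function(ids) {
    if (length(ids) == 0) return(character(0))
    b <- bacs[match(ids, bacs$bac_id), , drop = FALSE]
    sort(unique(c(sprintf("P%02d", b$plate), paste0("R", b$row),
                  sprintf("C%02d", b$column))))
  })
  truth
}

# Ground-truth island labels by positional sweep over BAC footprints within
# each contig (independent of the graph-based detector): order placements by
# footprint start, chain neighbours whose footprint gap is below gap_bp, and
# call chains of two or more an island.
realized_islands <- function(truth, map, gap_bp = 150e3) {
  truth$is_island <- FALSE
  truth$island_id <- NA_character_
  covered <- which(!truth$in_gap)
  if (length(covered) == 0) return(truth)
  bacs <- map$bacs
  fp_start <- map_dbl(truth$bac_ids[covered], function(ids) {
    min(bacs$start_bp[match(ids, bacs$bac_id)])
  })
  fp_end <- map_dbl(truth$bac_ids[covered], function(ids) {
    max(bacs$end_bp[match(ids, bacs$bac_id)])
  })
  df <- tibble(idx = covered, contig = truth$contig_id[covered],
               start = fp_start, end = fp_end)
  isl <- 0L
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    reach <- cummax(sub$end)
    new_chain <- c(TRUE, sub$start[-1] - reach[-nrow(sub)] >= gap_bp)
    chain <- cumsum(new_chain)
    for (ch in unique(chain)) {
      members <- sub$idx[chain == ch]
      if (length(members) >= 2) {
        isl <- isl + 1L
        truth$is_island[members] <- TRUE
        truth$island_id[members] <- sprintf("true_isl_%04d", isl)
      }
    }
  }
  truth
}

#' Inject repeat-derived probes into a truth set
#'
#' Gives every probe a random 60-mer sequence and replaces the sequences of
#' `n_te_probes` designated extra probes with mutated 60-mer substrings of
#' library repeats (about 90% identity, well above the 80%/45 nt filter
#' rule). Repeat probes hybridise in many unrelated pools and must be caught
#' by [te_filter()] rather than deconvolved.
#'
#' @param truth A `truth_set` from [place_genes()].
#' @param library A repeat library (data frame `repeat_id`, `sequence`),
#'   e.g. from [simulate_repeat_library()].
#' @param cfg A [sim_config()].
#' @return `truth`, with attributes `"sequences"` (tibble `probe_id`,
#'   `sequence`, `is_te`) and `"te_probes"`.
#' @export
inject_te_probes <- function(truth, library, cfg) {
  gene_probes <- unique(truth$probe_id)
  seqs <- tibble(probe_id = gene_probes,
                 sequence = random_dna(length(gene_probes), 60),
                 is_te = FALSE)
  if (cfg$n_te_probes > 0) {
    library <- as_sequence_table(library, "repeat_id")
    te_ids <- sprintf("te_probe_%02d", seq_len(cfg$n_te_probes))
    te_seq <- map_chr(seq_len(cfg$n_te_probes), function(i) {
      rep_row <- library[sample(nrow(library), 1), ]
      src <- rep_row$sequence
      start <- sample(nchar(src) - 60 + 1, 1)
      mutate_dna(substr(src, start, start + 59), n_subs = 6)
    })
    seqs <- bind_rows(seqs, tibble(probe_id = te_ids, sequence = te_seq, is_te = TRUE))
  }
  attr(truth, "sequences") <- seqs
  attr(truth, "te_probes") <- seqs$probe_id[seqs$is_te]
  truth
}

random_dna <- function(n, width) {
  map_chr(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  })
}

mutate_dna <- function(seq, n_subs) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a repeat library
#' @param n_repeats Number of repeat sequences.
#' @param length_bp Length of each repeat.
#' @return A tibble `repeat_id`, `sequence`.
#' @export
simulate_repeat_library <- function(n_repeats = 5, length_bp = 1000) {
  tibble(repeat_id = sprintf("repeat_%02d", seq_len(n_repeats)),
         sequence = random_dna(n_repeats, length_bp))
}

#' Simulate the probe-by-pool hybridisation signal matrix
#'
#' Every cell holds a background draw plus, for each BAC that both contains
#' the probe's gene and belongs to the pool, a contribution
#' `base_signal * (1 - decrease(identity)) * abundance(BAC)`. The decrease is
#' piecewise linear in identity: 0 at 100%, a per-probe draw from
#' `attenuation_range` at 90%, and total loss at or below `floor_identity`.
#' Per-BAC abundance factors are log-normal with mean 1 and the configured
#' CV. Repeat probes instead light up a random `te_pool_fraction` of all
#' pools.
#'
#' @param truth A `truth_set` from [place_genes()] (optionally after
#'   [inject_te_probes()]).
#' @param map The matching [physical_map()].
#' @param cfg A [sim_config()].
#' @return A raw [signal_matrix()]; per-BAC abundance factors and per-probe
#'   attenuation draws are kept in attributes `"abundance"` and
#'   `"attenuation"`.
#' @export
simulate_signals <- function(truth, map, cfg) {
  layout <- pool_layout(map, cfg$n_plates, cfg$n_rows, cfg$n_cols)
  te_probes <- attr(truth, "te_probes") %||% character(0)
  probes <- c(unique(truth$probe_id), te_probes)
  n <- length(probes)
  p <- nrow(layout)

  bg <- cfg$background
  m <- if (bg$scale > 0) {
    matrix(bg$scale * rlnorm(n * p, bg$meanlog, bg$sdlog), n, p)
  } else {
    matrix(0, n, p)
  }
  rownames(m) <- probes
  colnames(m) <- layout$pool_id

  cv <- cfg$bac_abundance_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    abundance <- setNames(rlnorm(nrow(map$bacs), -sdlog^2 / 2, sdlog), map$bacs$bac_id)
  } else {
    abundance <- setNames(rep(1, nrow(map$bacs)), map$bacs$bac_id)
  }

  d90 <- setNames(runif(n, cfg$attenuation_range[1], cfg$attenuation_range[2]), probes)
  decrease <- function(identity, d) {
    if (identity >= 100) 0
    else if (identity >= 90) d * (100 - identity) / 10
    else if (identity > cfg$floor_identity) d + (1 - d) * (90 - identity) / (90 - cfg$floor_identity)
    else 1
  }

  bac_pools <- map$bacs
  bac_pools$pp <- sprintf("P%02d", bac_pools$plate)
  bac_pools$rp <- paste0("R", bac_pools$row)
  bac_pools$cp <- sprintf("C%02d", bac_pools$column)
  pool_index <- setNames(seq_len(p), layout$pool_id)

  for (i in seq_len(nrow(truth))) {
    ids <- truth$bac_ids[[i]]
    if (length(ids) == 0) next
    dec <- decrease(truth$identity[i], d90[[truth$probe_id[i]]])
    sig <- cfg$base_signal * (1 - dec)
    if (sig <= 0) next
    ri <- match(truth$probe_id[i], probes)
    for (b in ids) {
      bi <- match(b, bac_pools$bac_id)
      cols <- pool_index[c(bac_pools$pp[bi], bac_pools$rp[bi], bac_pools$cp[bi])]
      m[ri, cols] <- m[ri, cols] + sig * abundance[[b]]
    }
  }

  for (tp in te_probes) {
    hot <- runif(p) < cfg$te_pool_fraction
    m[tp, hot] <- m[tp, hot] + cfg$base_signal * runif(sum(hot), 0.2, 0.8)
  }

  sm <- signal_matrix(m, layout, state = "raw")
  attr(sm, "abundance") <- abundance
  attr(sm, "attenuation") <- d90
  sm
}

#' Run the full synthetic experiment generator
#'
#' Seeds the RNG once from `cfg$seed`, then simulates the physical map,
#' gene placements, repeat probes and the signal matrix. Identical
#' configurations and seeds give identical results.
#'
#' @param cfg A [sim_config()].
#' @return A `pool_experiment` list: `cfg`, `map`, `layout`, `truth`,
#'   `library`, `signals`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  map <- simulate_physical_map(cfg)
  truth <- place_genes(cfg, map)
  library <- simulate_repeat_library()
  truth <- inject_te_probes(truth, library, cfg)
  signals <- simulate_signals(truth, map, cfg)
  structure(
    list(cfg = cfg, map = map, layout = attr(signals, "layout"),
         truth = truth, library = library, signals = signals),
    class = "pool_experiment"
  )
}

#' @export
print.pool_experiment <- function(x, ...) {
  cat("<pool_experiment> ", nrow(x$map$bacs), " BACs, ",
      length(unique(x$truth$probe_id)), " gene probes, ",
      nrow(x$signals), " x ", nrow(x$layout), " signal matrix\n", sep = "")
  invisible(x)
}

#' Ground-truth loci from a truth set
#'
#' Converts the covered placements of a truth set into a locus table of the
#' same shape [build_loci()] produces (BAC footprints, contigs, bins), for
#' recovery analyses that compare detected loci against the ground truth.
#'
#' @param truth A `truth_set` from [place_genes()].
#' @param map The matching [physical_map()].
#' @return A locus tibble with `locus_id`, `probe_id`, `bac_ids`, `n_bacs`,
#'   `contig_id`, `start_bp`, `end_bp`, `bin`, `duplicated`, `is_island`,
#'   `island_id`.
#' @export
loci_from_truth <- function(truth, map) {
  covered <- truth[!truth$in_gap, , drop = FALSE]
  bacs <- map$bacs
  tibble(
    locus_id = paste0(covered$probe_id, "@", seq_len(nrow(covered))),
    probe_id = covered$probe_id,
    bac_ids = covered$bac_ids,
    n_bacs = covered$n_bacs,
    contig_id = covered$contig_id,
    start_bp = map_dbl(covered$bac_ids, function(ids) {
      min(bacs$start_bp[match(ids, bacs$bac_id)])
    }),
    end_bp = map_dbl(covered$bac_ids, function(ids) {
      max(bacs$end_bp[match(ids, bacs$bac_id)])
    }),
    bin = bacs$bin[match(map_chr(covered$bac_ids, 1), bacs$bac_id)],
    duplicated = covered$duplicated,
    is_island = covered$is_island,
    island_id = covered$island_id
  )
}

#' Simulate reference-map labels for synteny/collinearity recovery
#'
#' Attaches a reference chromosome and position to each locus: with
#' probability `1 - nonsyntenic_fraction` the locus goes to the orthologous
#' chromosome at a position monotone in its physical position (plus noise),
#' otherwise to a random other chromosome at a random position.
#'
#' @param loci A locus tibble with `start_bp`.
#' @param nonsyntenic_fraction Fraction placed off the orthologous
#'   chromosome.
#' @param ortholog_chr Name of the orthologous chromosome.
#' @param other_chromosomes Candidate non-syntenic chromosomes.
#' @param cm_per_mb Reference map scale.
#' @param noise_cm SD of positional noise on the orthologous chromosome.
#' @return `loci` with `ref_chr` and `ref_pos` columns.
#' @export
simulate_synteny_labels <- function(loci, nonsyntenic_fraction = 0.32,
                                    ortholog_chr = "3H",
                                    other_chromosomes = c("1H", "2H", "4H", "5H", "6H", "7H"),
                                    cm_per_mb = 0.2, noise_cm = 2) {
  n <- nrow(loci)
  off <- runif(n) < nonsyntenic_fraction
  loci$ref_chr <- ifelse(off, sample(other_chromosomes, n, replace = TRUE), ortholog_chr)
  base_cm <- loci$start_bp / 1e6 * cm_per_mb
  loci$ref_pos <- ifelse(off, runif(n, 0, max(base_cm, na.rm = TRUE)),
                         pmax(0, base_cm + rnorm(n, 0, noise_cm)))
  loci
}
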