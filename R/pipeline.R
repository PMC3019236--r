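#' Run the full anchoring pipeline
#'
#' Drives simulate (or read) -> repeat filter -> normalise -> score ->
#' deconvolve -> locus building -> bin assignment -> gene-space and
#' (optionally) comparative statistics, and collects everything into a
#' single report. Deterministic given the same configuration and seed. Any
#' stage failure aborts with the stage named.
#'
#' Configuration (a YAML file path or a list):
#' \describe{
#'   \item{seed}{integer, used for all randomness.}
#'   \item{simulate}{list of [sim_config()] overrides (default: simulate).}
#'   \item{inputs}{alternatively, paths `physical_map` and `signals` to TSV
#'     files to analyse instead of simulating.}
#'   \item{scoring}{character vector of methods to apply, in precedence
#'     order, from `"automated"`, `"boxplot"`, `"semi_automated"`,
#'     `"manual"`. Mandatory: an empty selection is an error.}
#'   \item{normalize}{logical, apply the two-step median normalisation
#'     (default `TRUE`).}
#'   \item{te_filter}{logical, filter repeat probes before locus building
#'     (default `TRUE` when sequences are available).}
#'   \item{island_gap_bp}{island separation threshold (default 150000).}
#'   \item{comparative}{optional list with `nonsyntenic_fraction` to attach
#'     simulated reference labels and run synteny/collinearity.}
#'   \item{out_dir}{optional output directory for the JSON report and TSV
#'     tables.}
#' }
#'
#' @param config A list or the path of a YAML file.
#' @return A `pipeline_report` list with elements `config`, `counts`,
#'   `loci`, `bin_stats`, `islands`, `gradient`, `comparative`, `recovery`
#'   and `thresholds`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  methods <- config$scoring
  if (is.null(methods) || length(methods) == 0) {
    abort("pipeline stage 'configure' failed: no scoring method selected")
  }
  bad <- setdiff(methods, c("automated", "boxplot", "semi_automated", "manual"))
  if (length(bad) > 0) {
    abort(paste0("pipeline stage 'configure' failed: unknown scoring method(s): ",
                 paste(bad, collapse = ", ")))
  }

  simulated <- is.null(config$inputs)
  exp <- stage("inputs", {
    if (simulated) {
      args <- config$simulate %||% list()
      if (!is.null(config$seed)) args$seed <- config$seed
      simulate_experiment(do.call(sim_config, args))
    } else {
      map <- read_physical_map(config$inputs$physical_map)
      layout <- pool_layout(map)
      signals <- read_signal_matrix(config$inputs$signals, layout)
      list(map = map, layout = layout, signals = signals, truth = NULL, cfg = NULL)
    }
  })

  te <- stage("te_filter", {
    seqs <- attr(exp$truth, "sequences")
    do_filter <- config$te_filter %||% !is.null(seqs)
    if (isTRUE(do_filter) && !is.null(seqs) && !is.null(exp$library)) {
      te_filter(seqs, exp$library)
    } else {
      NULL
    }
  })
  flagged <- if (!is.null(te)) te$probe_id[te$flagged] else character(0)

  sm <- stage("normalize", {
    if (isTRUE(config$normalize %||% TRUE)) normalize_signals(exp$signals) else exp$signals
  })

  k <- config$automated_k %||% c(plate = 2.8, row = 2.5, column = 3.0)
  if (is.list(k)) k <- unlist(k)
  addresses <- stage("score_and_deconvolve", {
    resolved <- character(0)
    parts <- list()
    auto_scores <- NULL
    for (meth in methods) {
      part <- switch(meth,
        automated = {
          auto_scores <- score_automated(sm, k = k)
          resolve_addresses(auto_scores, exp$layout, exp$map)
        },
        boxplot = {
          bx <- resolve_addresses(score_boxplot(sm), exp$layout, exp$map)
          # less stringent method: keep only the most robust calls,
          # i.e. probes resolving onto 2-3 overlapping BACs
          bx[bx$resolution %in% c("overlapping_pair", "overlapping_triple"), ,
             drop = FALSE]
        },
        semi_automated = {
          if (is.null(auto_scores)) auto_scores <- score_automated(sm, k = k)
          complete_semi_automated(auto_scores, exp$layout, exp$map)
        },
        manual = {
          if (is.null(auto_scores)) auto_scores <- score_automated(sm, k = k)
          complete_manual(auto_scores, exp$layout, exp$map)
        }
      )
      part <- part[!(part$probe_id %in% c(resolved, flagged)), , drop = FALSE]
      resolved <- c(resolved, unique(part$probe_id))
      parts[[meth]] <- part
    }
    bind_rows(parts)
  })

  loci <- stage("build_loci", {
    loci <- build_loci(addresses, exp$map)
    assign_bins(loci, exp$map)
  })

  bin_lengths <- stage("bin_lengths", {
    exp$map$contigs %>%
      filter(!is.na(.data$bin)) %>%
      group_by(.data$bin) %>%
      summarise(contig_length_mb = sum(.data$length_bp) / 1e6, .groups = "drop") %>%
      arrange(match(.data$bin, exp$map$bins$bin))
  })

  gap_bp <- config$island_gap_bp %||% 150e3
  islands <- stage("genespace", detect_islands(loci, exp$map, gap_bp = gap_bp))
  stats <- stage("genespace", {
    bs <- normalized_density(bin_density(loci, bin_lengths))
    isl <- island_bin_stats(islands, bin_lengths)
    bs$pct_island <- isl$pct_island
    bs$n_island_loci <- isl$n_island_loci
    bs$n_isolated_loci <- isl$n_isolated_loci
    if (all(c("start_bp", "end_bp") %in% names(exp$map$bins)) &&
        !anyNA(exp$map$bins$start_bp)) {
      centro <- centromere_of(exp$map)
      geom <- centromere_distance(exp$map$bins, centro)
      bs$midpoint_dist_mb <- geom$midpoint_dist_mb[match(bs$bin, geom$bin)]
    }
    bs
  })

  gradient <- if ("midpoint_dist_mb" %in% names(stats) && nrow(stats) >= 3 &&
                  sd(stats$density) > 0) {
    stage("gradient", gradient_tests(stats))
  } else NULL

  comparative <- NULL
  if (!is.null(config$comparative)) {
    comparative <- stage("comparative", {
      q <- config$comparative$nonsyntenic_fraction %||% 0.32
      lab <- simulate_synteny_labels(loci, nonsyntenic_fraction = q)
      syn <- synteny_summary(lab, ortholog_chr = "3H")
      synt <- lab[!is.na(lab$ref_chr) & lab$ref_chr == "3H" & !is.na(lab$bin), ,
                  drop = FALSE]
      blocks <- build_synteny_blocks(synt, exp$map$bins$bin)
      coll <- collinearity_summary(synt, blocks)
      list(synteny = syn, blocks = blocks, collinearity = coll)
    })
  }

  recovery <- if (!is.null(exp$truth)) {
    stage("recovery", recovery_summary(exp$truth, loci, exp$cfg))
  } else NULL

  report <- structure(
    list(
      config = list(seed = config$seed %||% (exp$cfg$seed %||% NA),
                    scoring = methods,
                    normalize = isTRUE(config$normalize %||% TRUE),
                    island_gap_bp = gap_bp,
                    n_flagged_te = length(flagged)),
      counts = attr(loci, "counts"),
      bin_summary = attr(loci, "summary"),
      loci = loci,
      bin_stats = stats,
      islands = attr(islands, "islands"),
      gradient = gradient,
      comparative = comparative,
      recovery = recovery,
      te = te
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# The centromere sits at the boundary between the two centromere-flanking
# (arm "C") bins; without arm labels, fall back to the chromosome midpoint.
centromere_of <- function(map) {
  arms <- map$bins$arm
  if (!anyNA(arms) && sum(arms == "C") >= 1) {
    map$bins$end_bp[which(arms == "C")[1]]
  } else {
    (min(map$bins$start_bp) + max(map$bins$end_bp)) / 2
  }
}

# Detection and address-recovery rates against the simulated ground truth.
# A placement is detectable when at least one MTP BAC contains it and its
# probe identity is above the attenuation floor; a detected locus is correct
# when all its BACs belong to the true covering set.
recovery_summary <- function(truth, loci, cfg) {
  floor_id <- if (!is.null(cfg)) cfg$floor_identity else 80
  single <- truth[!truth$duplicated, , drop = FALSE]
  detectable <- single[!single$in_gap & single$identity > floor_id, , drop = FALSE]
  locus_by_probe <- split(loci$bac_ids, loci$probe_id)
  detected <- detectable$probe_id %in% loci$probe_id
  correct <- map_lgl(seq_len(nrow(detectable)), function(i) {
    sets <- locus_by_probe[[detectable$probe_id[i]]]
    if (is.null(sets)) return(FALSE)
    any(map_lgl(sets, function(b) length(b) > 0 && all(b %in% detectable$bac_ids[[i]])))
  })
  tibble(
    n_placed = nrow(single),
    n_detectable = nrow(detectable),
    n_detected = sum(detected),
    n_correct = sum(correct),
    detection_rate = if (nrow(detectable) > 0) sum(detected) / nrow(detectable) else NA_real_,
    correct_rate = if (sum(detected) > 0) sum(correct) / sum(detected) else NA_real_,
    overall_detection_rate = if (nrow(single) > 0) sum(single$probe_id %in% loci$probe_id) / nrow(single) else NA_real_
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  loci: ", x$counts$n_loci, " (", x$counts$n_probes, " probes, ",
      x$counts$n_duplicated, " duplicated)\n", sep = "")
  if (!is.null(x$recovery)) {
    cat("  detection: ", x$recovery$n_detected, "/", x$recovery$n_detectable,
        " detectable placements\n", sep = "")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` plus TSV tables (`loci.tsv`, `bin_stats.tsv`,
#' `islands.tsv`) into `dir`. Output is byte-identical for identical
#' configurations and seeds.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci_flat <- report$loci
  loci_flat$bac_ids <- map_chr(loci_flat$bac_ids, paste, collapse = ",")
  readr::write_tsv(as_tibble(as.data.frame(loci_flat)), file.path(dir, "loci.tsv"))
  readr::write_tsv(as_tibble(as.data.frame(report$bin_stats)),
                   file.path(dir, "bin_stats.tsv"))
  readr::write_tsv(report$islands, file.path(dir, "islands.tsv"))
  json <- list(
    config = report$config,
    counts = report$counts,
    bin_summary = report$bin_summary,
    bin_stats = as.data.frame(report$bin_stats),
    recovery = report$recovery,
    gradient = if (!is.null(report$gradient)) {
      list(pearson = glance(report$gradient$pearson),
           uniformity = glance(report$gradient$uniformity))
    },
    comparative = if (!is.null(report$comparative)) {
      list(synteny = glance(report$comparative$synteny),
           collinearity = glance(report$comparative$collinearity))
    }
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
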