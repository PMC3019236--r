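test_that("the study-scale pool design gives 60 pools with the right loads", {
  cfg <- sim_config(seed = 1)
  set.seed(cfg$seed)
  map <- simulate_physical_map(cfg)
  layout <- pool_layout(map, cfg$n_plates, cfg$n_rows, cfg$n_cols)
  expect_equal(nrow(layout), 20 + 16 + 24)
  expect_equal(sum(layout$n_bacs[layout$axis == "plate"]), nrow(map$bacs))

  # with every well filled: 384 BACs per plate pool, 480 per row pool,
  # 320 per column pool
  wells <- expand.grid(plate = 1:20, row = LETTERS[1:16], column = 1:24,
                       stringsAsFactors = FALSE)
  full <- physical_map(tibble::tibble(
    bac_id = sprintf("f%04d", seq_len(nrow(wells))),
    plate = wells$plate, row = wells$row, column = wells$column,
    contig_id = sprintf("c%04d", seq_len(nrow(wells))),
    start_bp = (seq_len(nrow(wells)) - 1) * 1e5,
    end_bp = seq_len(nrow(wells)) * 1e5
  ))
  full_layout <- pool_layout(full, 20, 16, 24)
  expect_true(all(full_layout$n_bacs[full_layout$axis == "plate"] == 384))
  expect_true(all(full_layout$n_bacs[full_layout$axis == "row"] == 480))
  expect_true(all(full_layout$n_bacs[full_layout$axis == "column"] == 320))
})

test_that("full coverage with zero overlap tiles the chromosome exactly", {
  cfg <- sim_config(seed = 2, chromosome_length_bp = 50e6,
                    mtp_coverage_fraction = 1, mtp_overlap_fraction = 0,
                    bac_length_jitter = 0, n_contigs = 20,
                    unbinned_contig_fraction = 0)
  set.seed(cfg$seed)
  map <- simulate_physical_map(cfg)
  expect_equal(sum(map$bacs$end_bp - map$bacs$start_bp), 50e6)
  expect_equal(nrow(map$overlaps), 0L) # half-open abutment, no overlap
  ctg <- map$contigs[order(map$contigs$start_bp), ]
  expect_equal(ctg$start_bp[-1], ctg$end_bp[-nrow(ctg)]) # contigs abut
})

test_that("capacity overflow is an error", {
  cfg <- sim_config(seed = 1, n_plates = 2, n_rows = 4, n_cols = 4)
  set.seed(1)
  expect_error(simulate_physical_map(cfg), "capacity")
})

test_that("a degenerate gradient gives uniform positions", {
  cfg <- sim_config(seed = 3, density_gradient_ratio = 1,
                    island_fraction_distal = 0, island_fraction_proximal = 0,
                    isolation_bp = 0, n_genes = 5000, duplication_prob = 0)
  set.seed(cfg$seed)
  map <- simulate_physical_map(cfg)
  truth <- place_genes(cfg, map)
  ks <- suppressWarnings(stats::ks.test(truth$position_bp, "punif", 0,
                                        cfg$chromosome_length_bp))
  expect_gt(ks$p.value, 0.01)
})

test_that("a twofold gradient doubles the outer-decile density", {
  ratios <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, density_gradient_ratio = 2,
                      island_fraction_distal = 0, island_fraction_proximal = 0,
                      isolation_bp = 0, n_genes = 2000, duplication_prob = 0)
    set.seed(cfg$seed)
    map <- simulate_physical_map(cfg)
    truth <- place_genes(cfg, map)
    len <- cfg$chromosome_length_bp
    C <- cfg$centromere_fraction * len
    d <- ifelse(truth$position_bp < C, (C - truth$position_bp) / C,
                (truth$position_bp - C) / (len - C))
    sum(d > 0.9) / sum(d < 0.1)
  }, numeric(1))
  # expected count ratio for a linear 1..2 gradient: 1.95 / 1.05 = 1.857
  expect_gt(mean(ratios), 1.857 * 0.85)
  expect_lt(mean(ratios), 1.857 * 1.15)
})

test_that("attenuation arithmetic matches the hand example and truth pools", {
  # identity 90%, base 100, decrease fixed at 0.86 -> +14.0 over background
  cfg <- sim_config(seed = 4, n_genes = 30, duplication_prob = 0,
                    n_te_probes = 0, bac_abundance_cv = 0,
                    background = list(meanlog = 0, sdlog = 0.25, scale = 0),
                    attenuation_range = c(0.86, 0.86),
                    identity_distribution = list(mean = 90, sd = 0, min = 90, max = 90))
  ex <- simulate_experiment(cfg)
  m <- as.matrix(ex$signals)
  covered <- ex$truth[!ex$truth$in_gap & ex$truth$n_bacs == 1, ]
  expect_gt(nrow(covered), 0)
  for (i in seq_len(nrow(covered))) {
    vals <- m[covered$probe_id[i], covered$expected_pools[[i]]]
    expect_equal(unname(vals), rep(14, 3), tolerance = 1e-9)
  }
  # probes in MTP gaps give background-only (here zero) rows
  gap_probes <- ex$truth$probe_id[ex$truth$in_gap]
  if (length(gap_probes) > 0) {
    expect_true(all(m[gap_probes, ] == 0))
  }
})

test_that("noiseless positive pools equal the expected pools from truth", {
  cfg <- sim_config(seed = 5, n_genes = 50, duplication_prob = 0,
                    n_te_probes = 0, bac_abundance_cv = 0,
                    background = list(meanlog = 0, sdlog = 0.25, scale = 0),
                    identity_distribution = list(mean = 100, sd = 0, min = 100, max = 100))
  ex <- simulate_experiment(cfg)
  m <- as.matrix(ex$signals)
  for (i in seq_len(nrow(ex$truth))) {
    got <- sort(colnames(m)[m[ex$truth$probe_id[i], ] > 0])
    expect_equal(got, ex$truth$expected_pools[[i]])
  }
})

test_that("the generator is reproducible from its seed", {
  cfg <- sim_config(seed = 11, n_genes = 60, n_contigs = 40,
                    chromosome_length_bp = 200e6)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_equal(as.matrix(ex1$signals), as.matrix(ex2$signals))
  expect_equal(ex1$truth$position_bp, ex2$truth$position_bp)
  expect_equal(ex1$map$bacs, ex2$map$bacs)
})

test_that("repeat-probe injection is optional and closes the loop with te_filter", {
  cfg0 <- sim_config(seed = 6, n_genes = 20, n_te_probes = 0)
  set.seed(cfg0$seed)
  map <- simulate_physical_map(cfg0)
  truth <- place_genes(cfg0, map)
  lib <- simulate_repeat_library()
  t0 <- inject_te_probes(truth, lib, cfg0)
  expect_length(attr(t0, "te_probes"), 0)
  expect_equal(t0$position_bp, truth$position_bp)

  cfg5 <- sim_config(seed = 6, n_genes = 20, n_te_probes = 5)
  t5 <- inject_te_probes(truth, lib, cfg5)
  seqs <- attr(t5, "sequences")
  flags <- te_filter(seqs, lib)
  expect_true(all(flags$flagged[flags$probe_id %in% attr(t5, "te_probes")]))
  expect_false(any(flags$flagged[!flags$probe_id %in% attr(t5, "te_probes")]))
})

test_that("an all-island placement is fully recovered by island detection", {
  cfg <- sim_config(seed = 8, n_genes = 200, island_fraction_distal = 1,
                    island_fraction_proximal = 1, island_gap_bp = 5e4,
                    duplication_prob = 0)
  set.seed(cfg$seed)
  map <- simulate_physical_map(cfg)
  truth <- place_genes(cfg, map)
  loci <- loci_from_truth(truth, map)
  det <- detect_islands(loci, map, gap_bp = 150e3)
  # graph detector agrees with the generator's positional sweep everywhere
  expect_equal(det$is_island, loci$is_island)
  # and essentially everything is an island (clusters truncated by an MTP
  # gap can leave the odd covered member isolated)
  expect_gt(mean(det$is_island), 0.95)
})
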