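test_that("marker linking keeps only best hits passing the 85%/100 nt rule", {
  loci <- tibble::tibble(probe_id = c("p1", "p2", "p3"), locus_id = c("l1", "l2", "l3"))
  gmap <- tibble::tibble(marker_id = c("m1", "m2", "m3"),
                         chromosome = c("3H", "3H", "2H"),
                         position_cm = c(10, 50, 5))
  hits <- tibble::tribble(
    ~probe_id, ~marker_id, ~identity_pct, ~length_nt,
    "p1", "m1", 90, 120,   # passes
    "p2", "m2", 90, 80,    # too short
    "p3", "m2", 88, 150,   # passes, but beaten on identity
    "p3", "m3", 92, 110    # best passing hit
  )
  out <- attach_map_positions(loci, gmap, hits)
  expect_equal(out$ref_chr, c("3H", NA, "2H"))
  expect_equal(out$ref_pos, c(10, NA, 5))
})

test_that("synteny summary partitions mapped loci", {
  loci <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:12),
    bin = rep(c("binS", "binL", NA), 4),
    ref_chr = c(rep("3H", 8), rep("2H", 3), NA)
  )
  syn <- synteny_summary(loci, "3H")
  ov <- glance(syn)
  expect_equal(ov$n_mapped, 11L)
  expect_equal(ov$n_syntenic + ov$n_nonsyntenic, ov$n_mapped)
  expect_equal(ov$pct_syntenic, 100 * 8 / 11)
  expect_equal(sum(tidy(syn)$n_syntenic + tidy(syn)$n_other), 8L) # binned only
  # all loci on the orthologous chromosome -> 100%
  all3h <- synteny_summary(dplyr::mutate(loci, ref_chr = "3H"), "3H")
  expect_equal(glance(all3h)$pct_syntenic, 100)
})

test_that("bias tests match hand arithmetic and the stats oracles", {
  # proportional counts: no deviation, perfect correlation
  b0 <- bias_tests(c(a = 10, b = 10), c(a = 100, b = 100))
  expect_equal(b0$chisq$statistic, 0)
  expect_equal(b0$chisq$p_value, 1)

  b <- bias_tests(c(a = 8, c = 12, e = 25), c(a = 100, c = 100, e = 300))
  expect_equal(b$chisq$statistic, 1 / 9 + 9 / 9 + 4 / 27, tolerance = 1e-12)
  expect_equal(b$chisq$df, 2)
  ref <- suppressWarnings(stats::chisq.test(c(8, 12, 25), p = c(.2, .2, .6)))
  expect_equal(b$chisq$statistic, unname(ref$statistic))
  expect_equal(b$chisq$p_value, ref$p.value)
  expect_equal(b$pearson$r, stats::cor(c(8, 12, 25), c(100, 100, 300)))

  expect_warning(bias_tests(c(a = 5, b = 5, c = 2), c(a = 10, b = 10, c = 0)),
                 "pooled")
})

test_that("uniformity chi-square builds expected values from bin totals", {
  u0 <- chisq_uniformity(c(5, 5), c(10, 10))
  expect_equal(u0$statistic, 0)
  expect_equal(u0$p_value, 1)

  # per-bin syntenic counts over per-bin mapped totals: 73% on average
  bins <- wheat3b_bin_table()
  u <- chisq_uniformity(bins$barley_3h, bins$barley_3h + bins$barley_other)
  expect_equal(round(100 * u$proportion), 73)

  # 8-bin worked example, cross-checked against stats::chisq.test
  o <- c(10, 12, 14, 9, 15, 25, 13, 55)
  t8 <- c(19, 16, 25, 10, 18, 35, 18, 69)
  u8 <- chisq_uniformity(o, t8)
  expect_equal(u8$statistic, 3.182036, tolerance = 1e-6)
  expect_equal(u8$df, 7)
  expect_equal(u8$p_value, 0.8676672, tolerance = 1e-6)
  ref <- suppressWarnings(stats::chisq.test(o, p = t8 / sum(t8)))
  expect_equal(u8$statistic, unname(ref$statistic))
  expect_equal(u8$p_value, ref$p.value)

  # zero exactly when observed/total is constant across bins
  expect_equal(chisq_uniformity(c(3, 6, 9), c(10, 20, 30))$statistic, 0)
})

test_that("pearson and welch wrappers agree with the stats oracles", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_test(x, 2 * x)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  p <- pearson_test(x, c(2, 1, 4, 3))
  expect_equal(p$r, 0.6)
  expect_equal(p$p_value, stats::cor.test(x, c(2, 1, 4, 3))$p.value)
  expect_error(pearson_test(c(1, 1, 1), x[1:3]), "constant")

  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  w <- welch_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(w$t, -2.19089, tolerance = 1e-5)
  expect_equal(w$df, 6)
  ref <- stats::t.test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(w$p_value, ref$p.value)
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
})

test_that("synteny blocks follow bin order and exclude intruders", {
  bins <- c("b1", "b2", "b3")
  # perfectly sorted positions give disjoint blocks in bin order
  loci <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:9),
    bin = rep(bins, each = 3),
    ref_pos = c(1, 2, 3, 11, 12, 13, 21, 22, 23)
  )
  blocks <- build_synteny_blocks(loci, bins)
  expect_equal(blocks$ref_min, c(1, 11, 21))
  expect_equal(blocks$ref_max, c(3, 13, 23))
  expect_true(all(blocks$ref_max[-3] < blocks$ref_min[-1]))
  coll <- collinearity_summary(loci, blocks)
  expect_equal(glance(coll)$pct_collinear, 100)

  # one b1 locus sitting inside b2's range is excluded from b1's block
  intr <- loci
  intr$ref_pos[3] <- 12.5
  blocks2 <- build_synteny_blocks(intr, bins)
  expect_equal(blocks2$ref_max[1], 2) # the intruder no longer stretches b1
  coll2 <- collinearity_summary(intr, blocks2)
  expect_equal(glance(coll2)$n_collinear, 8L)
  expect_false(coll2$collinear[3])

  # single bin: block spans [min, max]
  single <- tibble::tibble(locus_id = c("a", "b", "c"), bin = "b1",
                           ref_pos = c(10, 20, 30))
  b1 <- build_synteny_blocks(single, "b1")
  expect_equal(c(b1$ref_min, b1$ref_max), c(10, 30))
})

test_that("collinearity is invariant under order-preserving position transforms", {
  set.seed(13)
  bins <- c("b1", "b2", "b3", "b4")
  loci <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:40),
    bin = sample(bins, 40, replace = TRUE),
    ref_pos = runif(40, 0, 100)
  )
  base <- collinearity_summary(loci, build_synteny_blocks(loci, bins))
  warped <- dplyr::mutate(loci, ref_pos = exp(ref_pos / 20))
  after <- collinearity_summary(warped, build_synteny_blocks(warped, bins))
  expect_equal(base$collinear, after$collinear)
})

test_that("synteny recovery matches the simulated non-syntenic fraction", {
  q <- 0.3
  rates <- vapply(1:20, function(s) {
    set.seed(s)
    loci <- tibble::tibble(locus_id = sprintf("l%04d", 1:1000),
                           start_bp = sort(runif(1000, 0, 8e8)))
    lab <- simulate_synteny_labels(loci, nonsyntenic_fraction = q)
    glance(synteny_summary(lab, "3H"))$pct_syntenic / 100
  }, numeric(1))
  # binomial CI around 1 - q at n = 1000 per seed, averaged over 20 seeds
  expect_lt(abs(mean(rates) - (1 - q)), 3 * sqrt(q * (1 - q) / (1000 * 20)))
  expect_true(all(abs(rates - (1 - q)) < 4 * sqrt(q * (1 - q) / 1000)))
})
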