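test_that("bin densities reproduce the bundled wheat 3B table to 2 decimals", {
  bins <- wheat3b_bin_table()
  bs <- bin_density(dplyr::select(bins, bin, n_loci), dplyr::select(bins, bin, contig_length_mb))
  printed <- c(0.84, 1.00, 0.91, 0.58, 0.79, 1.04, 1.00, 1.06)
  expect_equal(round(bs$density, 2), printed)
  expect_equal(round(attr(bs, "overall")$density, 2), 0.93) # 519 / 556.2
  expect_equal(attr(bs, "overall")$n_loci, 519)
  expect_error(bin_density(bins, tibble::tibble(bin = "x", contig_length_mb = 0)),
               "> 0")
})

test_that("normalised densities use unrounded densities and average to 1", {
  bs <- normalized_density(bin_density(
    dplyr::select(wheat3b_bin_table(), bin, n_loci),
    dplyr::select(wheat3b_bin_table(), bin, contig_length_mb)
  ))
  expect_equal(round(bs$normalized_density[bs$bin == "3BS8-0.78-1.00"], 3), 0.928)
  expect_equal(round(bs$normalized_density[bs$bin == "3BL7-0.63-1.00"], 3), 1.176)
  expect_equal(mean(bs$normalized_density), 1)
  # equal densities normalise to exactly 1 everywhere
  eq <- normalized_density(tibble::tibble(density = c(2, 2, 2)))
  expect_equal(eq$normalized_density, c(1, 1, 1))
})

test_that("centromere distances are bin-midpoint distances in Mb", {
  bins <- tibble::tibble(bin = c("a", "b"), start_bp = c(0, 10e6),
                         end_bp = c(10e6, 30e6))
  out <- centromere_distance(bins, 0)
  expect_equal(out$midpoint_dist_mb, c(5, 20))
  # a bin spanning the centromere symmetrically sits at distance 0
  sym <- centromere_distance(tibble::tibble(bin = "c", start_bp = 5e6,
                                            end_bp = 15e6), 10e6)
  expect_equal(sym$midpoint_dist_mb, 0)
})

test_that("gradient tests wire density, distance and uniformity together", {
  bs <- tibble::tibble(
    bin = letters[1:4], n_loci = c(10, 20, 30, 40),
    contig_length_mb = c(10, 10, 10, 10),
    density = c(1, 2, 3, 4), midpoint_dist_mb = c(10, 20, 30, 40)
  )
  gt <- gradient_tests(bs)
  expect_equal(gt$pearson$r, 1)
  expect_gt(gt$uniformity$statistic, 0)
  # equal densities: uniformity chi-square is 0 and the correlation errors
  eq <- dplyr::mutate(bs, n_loci = 10L, density = 1)
  expect_equal(chisq_uniformity(eq$n_loci, eq$contig_length_mb)$statistic, 0)
  expect_error(gradient_tests(eq), "constant")
})

test_that("island detection uses BAC intervals, transitivity and contig breaks", {
  map <- tiny_map()
  mk <- function(id, contig, s, e) {
    tibble::tibble(locus_id = id, probe_id = id, contig_id = contig,
                   start_bp = s, end_bp = e, bin = "binL")
  }
  # two loci on the same BAC interval form one island of 2
  same <- dplyr::bind_rows(mk("l1", "ctgB", 600000, 750000),
                           mk("l2", "ctgB", 600000, 750000))
  d1 <- detect_islands(same, map)
  expect_equal(d1$island_id[1], d1$island_id[2])
  expect_equal(attr(d1, "islands")$n_loci, 2L)

  # BAC intervals 200 kb apart stay isolated
  apart <- dplyr::bind_rows(mk("l1", "ctgB", 600000, 700000),
                            mk("l2", "ctgB", 900000, 950000))
  expect_true(all(is.na(detect_islands(apart, map)$island_id)))

  # chain with consecutive 100 kb gaps is one island of 3 by transitivity
  chain <- dplyr::bind_rows(mk("l1", "ctgB", 600000, 650000),
                            mk("l2", "ctgB", 750000, 800000),
                            mk("l3", "ctgB", 900000, 950000))
  d3 <- detect_islands(chain, map)
  expect_equal(length(unique(d3$island_id)), 1L)
  expect_equal(attr(d3, "islands")$n_loci, 3L)

  # the same loci on different contigs never chain
  split <- chain
  split$contig_id <- c("ctgB", "ctgC", "ctgB")
  d4 <- detect_islands(split, map)
  expect_true(all(is.na(d4$island_id)))
})

test_that("island components agree with a brute-force oracle", {
  set.seed(77)
  map <- tiny_map()
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    s <- sort(runif(n, 0, 2e6))
    loci <- tibble::tibble(
      locus_id = sprintf("l%02d", seq_len(n)), probe_id = locus_id,
      contig_id = sample(c("ctgB", "ctgC"), n, replace = TRUE),
      start_bp = s, end_bp = s + runif(n, 5e4, 2e5), bin = "binL"
    )
    det <- detect_islands(loci, map)
    comp <- oracle_islands(loci)
    sizes <- table(comp)
    want_island <- as.vector(sizes[as.character(comp)] >= 2)
    expect_equal(det$is_island, want_island)
    # partitions agree: same island iff same oracle component
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        same_det <- !is.na(det$island_id[i]) && !is.na(det$island_id[j]) &&
          det$island_id[i] == det$island_id[j]
        expect_equal(same_det, comp[i] == comp[j] && want_island[i])
      }
    }
  }
})

test_that("island membership is monotone in the gap threshold", {
  set.seed(78)
  map <- tiny_map()
  s <- sort(runif(12, 0, 2e6))
  loci <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:12), probe_id = locus_id,
    contig_id = "ctgB", start_bp = s, end_bp = s + 8e4, bin = "binL"
  )
  for (gaps in list(c(5e4, 1e5), c(1e5, 2e5), c(2e5, 4e5))) {
    small <- detect_islands(loci, map, gap_bp = gaps[1])
    large <- detect_islands(loci, map, gap_bp = gaps[2])
    # partition refinement: co-islanded at the small gap implies co-islanded
    # at the large gap
    for (i in 1:11) {
      for (j in (i + 1):12) {
        if (!is.na(small$island_id[i]) && !is.na(small$island_id[j]) &&
            small$island_id[i] == small$island_id[j]) {
          expect_true(large$island_id[i] == large$island_id[j])
        }
      }
    }
  }
})

test_that("per-bin island statistics add up", {
  map <- tiny_map()
  s <- c(6e5, 6.2e5, 1.2e6, 1.45e6)
  loci <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:4), probe_id = locus_id,
    contig_id = c("ctgB", "ctgB", "ctgC", "ctgC"),
    start_bp = s, end_bp = s + 1e5,
    bin = c("binL", "binL", "binL", "binL")
  )
  det <- detect_islands(loci, map)
  stats <- island_bin_stats(det, tibble::tibble(bin = "binL", contig_length_mb = 1))
  expect_equal(stats$n_island_loci + stats$n_isolated_loci, stats$n_loci)
  expect_equal(stats$island_density + stats$isolated_density, stats$density)
})

test_that("extrapolation projects densities and rescales to the target", {
  bs <- tibble::tibble(bin = c("a", "b"), n_loci = c(10, 20),
                       contig_length_mb = c(10, 10), density = c(1, 2))
  full <- tibble::tibble(bin = c("a", "b"), full_size_mb = c(10, 10))
  out <- extrapolate_density(bs, full, target_total = 60)
  expect_equal(out$projected_loci_scaled, c(20, 40))
  expect_equal(out$kb_per_gene, c(500, 250))
  expect_equal(sum(out$projected_loci_scaled), 60)

  # full sizes equal to contig lengths and target = observed total: identity
  id <- extrapolate_density(bs, tibble::tibble(bin = c("a", "b"),
                                               full_size_mb = c(10, 10)))
  expect_equal(id$projected_loci_scaled, c(10, 20))

  # doubling the target halves every kb-per-gene spacing
  out2 <- extrapolate_density(bs, full, target_total = 120)
  expect_equal(out2$kb_per_gene, out$kb_per_gene / 2)

  # missing full sizes: skipped with a notice
  expect_warning(res <- extrapolate_density(bs, full[1, ]), "skipped")
  expect_null(res)
})

test_that("tandem correction is the floored deficit of normalised densities", {
  expect_equal(tandem_correction(c(1, 1), c(1, 1)), c(0, 0))
  expect_equal(tandem_correction(0.5, 1), 0.5)
  expect_equal(round(tandem_correction(0.928, 1.190), 3), 0.22)
  expect_equal(tandem_correction(1.2, 1), 0) # floored at zero
  expect_true(is.na(tandem_correction(1, 0)))
})
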