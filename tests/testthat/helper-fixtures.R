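# Hand-built fixtures and brute-force oracles shared across the test files.

# 12-BAC map over three contigs plus one singleton, wells spread over
# 3 plates x 4 rows (A-D) x 3 columns. Intervals chosen so that adjacent
# BACs within a contig overlap by 50 kb.
tiny_map <- function() {
  bacs <- tibble::tribble(
    ~bac_id, ~plate, ~row, ~column, ~contig_id, ~start_bp, ~end_bp, ~bin,
    "b01", 1L, "A", 1L, "ctgA", 0, 150000, "binS",
    "b02", 1L, "A", 2L, "ctgA", 100000, 250000, "binS",
    "b03", 1L, "A", 3L, "ctgA", 200000, 350000, "binS",
    "b04", 1L, "B", 1L, "ctgA", 300000, 450000, "binS",
    "b05", 2L, "B", 2L, "ctgB", 600000, 750000, "binL",
    "b06", 2L, "C", 3L, "ctgB", 700000, 850000, "binL",
    "b07", 2L, "D", 1L, "ctgB", 800000, 950000, "binL",
    "b08", 3L, "A", 2L, "ctgB", 900000, 1050000, "binL",
    "b09", 3L, "B", 3L, "ctgC", 1200000, 1350000, "binL",
    "b10", 3L, "C", 1L, "ctgC", 1300000, 1450000, "binL",
    "b11", 3L, "D", 2L, "ctgC", 1400000, 1550000, "binL",
    "b12", 2L, "A", 3L, NA, NA, NA, NA
  )
  physical_map(bacs, bins = tibble::tibble(bin = c("binS", "binL"),
                                           arm = c("S", "L"),
                                           start_bp = c(0, 500000),
                                           end_bp = c(500000, 1600000)))
}

tiny_layout <- function(map = tiny_map()) pool_layout(map, 3, 4, 3)

# Minimal pool_layout for signal-matrix tests that do not involve a map.
make_layout <- function(pool_ids, axes, members = NULL) {
  if (is.null(members)) members <- rep(list(character(0)), length(pool_ids))
  structure(
    tibble::tibble(pool_id = pool_ids, axis = axes,
                   members = members, n_bacs = lengths(members)),
    geometry = c(plate = sum(axes == "plate"), row = sum(axes == "row"),
                 column = sum(axes == "column")),
    class = c("pool_layout", class(tibble::tibble()))
  )
}

# A layout with n_plate/n_row/n_col pools per axis, no members.
axis_layout <- function(n_plate = 20, n_row = 16, n_col = 24) {
  make_layout(
    c(sprintf("P%02d", seq_len(n_plate)), paste0("R", LETTERS[seq_len(n_row)]),
      sprintf("C%02d", seq_len(n_col))),
    rep(c("plate", "row", "column"), c(n_plate, n_row, n_col))
  )
}

# Build a one-probe signal matrix from per-axis value vectors.
one_probe_matrix <- function(layout, plate = NULL, row = NULL, column = NULL) {
  vals <- c(plate, row, column)
  m <- matrix(vals, nrow = 1, dimnames = list("probe_1", layout$pool_id))
  signal_matrix(m, layout, state = "probe_normalised")
}

# Hand-made scoring-result tibble (positives only).
make_scores <- function(probe_id, pools, method = "automated") {
  axis <- ifelse(grepl("^P", pools), "plate", ifelse(grepl("^R", pools), "row", "column"))
  structure(
    tibble::tibble(probe_id = probe_id, axis = axis, pool_id = pools,
                   value = NA_real_, threshold = NA_real_, pass = 1L,
                   method = method),
    method = method,
    class = c("pool_scores", class(tibble::tibble()))
  )
}

# Brute-force deconvolution oracle: enumerate every subset of ALL map BACs of
# size 1..3 whose well coordinates project exactly onto the positive pools
# and whose members pairwise overlap; resolved iff a unique subset exists at
# the smallest achievable size.
oracle_resolve <- function(map, plate_pools, row_pools, col_pools) {
  bacs <- map$bacs
  want_p <- sort(as.integer(sub("^P", "", plate_pools)))
  want_r <- sort(sub("^R", "", row_pools))
  want_c <- sort(as.integer(sub("^C", "", col_pools)))
  n <- nrow(bacs)
  for (size in 1:3) {
    if (size > n) break
    subsets <- utils::combn(n, size, simplify = FALSE)
    hits <- Filter(function(ix) {
      sub <- bacs[ix, , drop = FALSE]
      identical(sort(unique(sub$plate)), want_p) &&
        identical(sort(unique(sub$row)), want_r) &&
        identical(sort(unique(sub$column)), want_c) &&
        bacs_mutually_overlap(map, sub$bac_id)
    }, subsets)
    if (length(hits) == 1) return(sort(bacs$bac_id[hits[[1]]]))
    if (length(hits) > 1) return(NULL)
  }
  NULL
}

# Random small deconvolution instance on a 3x3x3 grid.
random_instance <- function() {
  n_bac <- sample(4:9, 1)
  wells <- sample(27, n_bac)
  plate <- (wells - 1) %/% 9 + 1
  rem <- (wells - 1) %% 9
  row <- LETTERS[rem %/% 3 + 1]
  column <- rem %% 3 + 1
  # one contig with random tiling so that some neighbours overlap
  starts <- cumsum(sample(c(50000, 120000, 200000), n_bac, replace = TRUE))
  ends <- starts + 150000
  map <- physical_map(tibble::tibble(
    bac_id = sprintf("x%02d", seq_len(n_bac)), plate = plate, row = row,
    column = column, contig_id = "ctg", start_bp = starts, end_bp = ends
  ))
  if (runif(1) < 0.6) {
    # positives derived from the coordinates of 1-2 actual BACs, so that
    # resolvable and near-resolvable patterns are well represented
    picks <- sample(n_bac, sample(1:2, 1))
    sets <- list(
      plate = sprintf("P%02d", unique(plate[picks])),
      row = paste0("R", unique(row[picks])),
      column = sprintf("C%02d", unique(column[picks]))
    )
  } else {
    k <- sample(1:4, 3, replace = TRUE)
    sets <- list(
      plate = sprintf("P%02d", sample(3, min(k[1], 3))),
      row = paste0("R", sample(LETTERS[1:3], min(k[2], 3))),
      column = sprintf("C%02d", sample(3, min(k[3], 3)))
    )
  }
  list(map = map, sets = sets)
}

# Brute-force island components: loci are connected when their BAC intervals
# lie on the same contig closer than gap_bp (edge-to-edge, half-open).
oracle_islands <- function(loci, gap_bp = 150e3) {
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (is.na(loci$contig_id[i]) || is.na(loci$contig_id[j])) next
      if (loci$contig_id[i] != loci$contig_id[j]) next
      gap <- max(loci$start_bp[i], loci$start_bp[j]) -
        min(loci$end_bp[i], loci$end_bp[j])
      if (gap < gap_bp) adj[i, j] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# Deterministic flanks that cannot extend an alignment: every base replaced
# by its "mismatch partner" relative to the reference continuation.
mismatching <- function(ref_chars) {
  swap <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  unname(swap[ref_chars])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
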