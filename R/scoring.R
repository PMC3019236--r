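#' Automated positive-pool scoring by iterative outlier thresholding
#'
#' For every probe and every pool axis, a threshold `mean + k * SD` is
#' computed over that axis's pools and every pool strictly above it is
#' called positive. The step is then repeated twice more (three passes in
#' total): previously called positives are deleted from the mean/SD
#' computation, the threshold is recomputed, and new positives above the new
#' threshold are added. The union over the passes is returned. The default
#' multipliers differ per axis (plate 2.8, row 2.5, column 3.0) because each
#' axis pools a different number of BACs.
#'
#' @param sm A [signal_matrix()] (normally `probe_normalised`).
#' @param k Named multipliers per axis.
#' @param passes Number of passes (default 3: the initial pass plus two
#'   repeats).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A `pool_scores` tibble with one row per positive call:
#'   `probe_id`, `axis`, `pool_id`, `value`, `threshold`, `pass`, `method`.
#'   A full audit of per-pass means, SDs and thresholds is kept in attribute
#'   `"audit"`.
#' @export
score_automated <- function(sm, k = c(plate = 2.8, row = 2.5, column = 3.0),
                            passes = 3, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  layout <- attr(sm, "layout")
  m <- as.matrix(sm)
  calls <- list()
  audit <- list()

  for (ax in c("plate", "row", "column")) {
    pools <- layout$pool_id[layout$axis == ax]
    if (length(pools) < 3) abort(paste0("axis '", ax, "' has fewer than 3 pools"))
    v <- m[, pools, drop = FALSE]
    pos <- matrix(FALSE, nrow(v), ncol(v))
    kk <- unname(k[[ax]])
    for (p in seq_len(passes)) {
      active <- !pos
      cnt <- rowSums(active)
      mu <- rowSums(v * active) / cnt
      ss <- rowSums(((v - mu)^2) * active)
      denom <- if (sd_type == "sample") pmax(cnt - 1, 0) else cnt
      s <- sqrt(ifelse(denom > 0, ss / denom, NA_real_))
      thr <- mu + kk * s
      thr[!is.finite(thr)] <- Inf
      new_pos <- (v > thr) & !pos
      audit[[length(audit) + 1]] <- tibble(
        probe_id = rownames(v), axis = ax, pass = p,
        mean = unname(mu), sd = unname(s), threshold = unname(thr)
      )
      if (any(new_pos)) {
        idx <- which(new_pos, arr.ind = TRUE)
        calls[[length(calls) + 1]] <- tibble(
          probe_id = rownames(v)[idx[, 1]], axis = ax,
          pool_id = pools[idx[, 2]], value = unname(v[idx]),
          threshold = unname(thr[idx[, 1]]), pass = p
        )
      }
      pos <- pos | new_pos
    }
  }

  res <- if (length(calls) > 0) bind_rows(calls) else
    tibble(probe_id = character(), axis = character(), pool_id = character(),
           value = numeric(), threshold = numeric(), pass = integer())
  res$method <- "automated"
  res <- arrange(res, .data$probe_id, .data$axis, .data$pool_id)
  structure(res, audit = bind_rows(audit), layout = layout, method = "automated",
            class = c("pool_scores", class(tibble())))
}

#' Boxplot positive-pool scoring
#'
#' For every probe and axis, pools whose value exceeds the upper boxplot
#' fence `Q3 + 1.5 * IQR` (quartiles by linear interpolation, type 7) are
#' called positive. This method is less stringent than [score_automated()];
#' downstream, calls derived from it are normally restricted to probes that
#' resolve onto two to three overlapping BACs.
#'
#' @param sm A [signal_matrix()].
#' @param coef Fence coefficient (default 1.5).
#' @param quantile_type Quantile algorithm, passed to [stats::quantile()].
#' @return A `pool_scores` tibble (see [score_automated()]).
#' @export
score_boxplot <- function(sm, coef = 1.5, quantile_type = 7) {
  layout <- attr(sm, "layout")
  m <- as.matrix(sm)
  calls <- list()
  for (ax in c("plate", "row", "column")) {
    pools <- layout$pool_id[layout$axis == ax]
    v <- m[, pools, drop = FALSE]
    qs <- t(apply(v, 1, quantile, probs = c(0.25, 0.75), type = quantile_type,
                  names = FALSE))
    fence <- qs[, 2] + coef * (qs[, 2] - qs[, 1])
    hit <- v > fence
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      calls[[length(calls) + 1]] <- tibble(
        probe_id = rownames(v)[idx[, 1]], axis = ax, pool_id = pools[idx[, 2]],
        value = unname(v[idx]), threshold = unname(fence[idx[, 1]]), pass = 1L
      )
    }
  }
  res <- if (length(calls) > 0) bind_rows(calls) else
    tibble(probe_id = character(), axis = character(), pool_id = character(),
           value = numeric(), threshold = numeric(), pass = integer())
  res$method <- "boxplot"
  res <- arrange(res, .data$probe_id, .data$axis, .data$pool_id)
  structure(res, layout = layout, method = "boxplot",
            class = c("pool_scores", class(tibble())))
}

#' Positive pools per probe, grouped by axis
#'
#' @param scores A `pool_scores` tibble.
#' @return A tibble with one row per probe: list columns `plate`, `row`,
#'   `column` of positive pool ids, and `n_pos` totals.
#' @export
positives_by_probe <- function(scores) {
  df <- as_tibble(as.data.frame(scores))
  if (nrow(df) == 0) {
    return(tibble(probe_id = character(), plate = list(), row = list(),
                  column = list(), n_pos = integer()))
  }
  df %>%
    group_by(.data$probe_id) %>%
    summarise(
      plate = list(sort(unique(.data$pool_id[.data$axis == "plate"]))),
      row = list(sort(unique(.data$pool_id[.data$axis == "row"]))),
      column = list(sort(unique(.data$pool_id[.data$axis == "column"]))),
      n_pos = dplyr::n_distinct(.data$pool_id),
      .groups = "drop"
    )
}

#' Semi-automated completion for probes with five positive pools
#'
#' Targets probes whose positives form a 2/2/1 pattern across the axes
#' (e.g. two plate pools, two row pools, one column pool), the signature of
#' a gene sitting on the overlap of two BACs whose wells differ on two axes.
#' All well combinations of the positive coordinates are enumerated, and the
#' probe is accepted if and only if exactly one pair of combinations names
#' two BACs that overlap on the physical map; both addresses are then
#' assigned. Anything else (no such pair, or several) leaves the probe
#' unresolved.
#'
#' @param scores A `pool_scores` tibble.
#' @param layout A [pool_layout()].
#' @param map A [physical_map()].
#' @return A tibble of BAC addresses: `probe_id`, `bac_id`, `plate`, `row`,
#'   `column`, `method = "semi_automated"`, `resolution = "overlapping_pair"`.
#' @export
complete_semi_automated <- function(scores, layout, map) {
  byp <- positives_by_probe(scores)
  out <- list()
  for (i in seq_len(nrow(byp))) {
    sizes <- sort(c(length(byp$plate[[i]]), length(byp$row[[i]]),
                    length(byp$column[[i]])))
    if (!(byp$n_pos[i] == 5 && identical(sizes, c(1L, 2L, 2L)))) next
    wells <- enumerate_wells(map, byp$plate[[i]], byp$row[[i]], byp$column[[i]])
    exist <- wells[!is.na(wells$bac_id), , drop = FALSE]
    if (nrow(exist) < 2) next
    prs <- combn(seq_len(nrow(exist)), 2)
    ok <- which(bacs_overlap(map, exist$bac_id[prs[1, ]], exist$bac_id[prs[2, ]]))
    if (length(ok) != 1) next # zero -> unresolvable; >1 -> ambiguous, no call
    pick <- exist[prs[, ok], , drop = FALSE]
    pick$probe_id <- byp$probe_id[i]
    pick$method <- "semi_automated"
    pick$resolution <- "overlapping_pair"
    out[[length(out) + 1]] <- pick
  }
  finalize_addresses(out)
}

#' Manual completion for probes with two positive pools
#'
#' Targets probes positive in exactly one pool on each of two axes, with the
#' third coordinate missing. Every value of the missing axis is enumerated;
#' the probe is accepted if and only if exactly one candidate well contains
#' an MTP BAC, which fixes the missing coordinate.
#'
#' @inheritParams complete_semi_automated
#' @return A tibble of BAC addresses with `method = "manual"`,
#'   `resolution = "unique"`.
#' @export
complete_manual <- function(scores, layout, map) {
  geometry <- attr(layout, "geometry")
  byp <- positives_by_probe(scores)
  out <- list()
  for (i in seq_len(nrow(byp))) {
    sizes <- c(plate = length(byp$plate[[i]]), row = length(byp$row[[i]]),
               column = length(byp$column[[i]]))
    if (!(byp$n_pos[i] == 2 && sum(sizes == 1) == 2 && sum(sizes == 0) == 1)) next
    missing_axis <- names(sizes)[sizes == 0]
    cand <- switch(missing_axis,
      plate = sprintf("P%02d", seq_len(geometry[["plate"]])),
      row = paste0("R", LETTERS[seq_len(geometry[["row"]])]),
      column = sprintf("C%02d", seq_len(geometry[["column"]]))
    )
    sets <- list(plate = byp$plate[[i]], row = byp$row[[i]], column = byp$column[[i]])
    sets[[missing_axis]] <- cand
    wells <- enumerate_wells(map, sets$plate, sets$row, sets$column)
    exist <- wells[!is.na(wells$bac_id), , drop = FALSE]
    if (nrow(exist) != 1) next
    exist$probe_id <- byp$probe_id[i]
    exist$method <- "manual"
    exist$resolution <- "unique"
    out[[length(out) + 1]] <- exist
  }
  finalize_addresses(out)
}

# All wells implied by per-axis positive pool ids, with the BAC found there
# (NA when the well is empty).
enumerate_wells <- function(map, plate_pools, row_pools, col_pools) {
  coords <- expand.grid(
    plate = as.integer(sub("^P", "", plate_pools)),
    row = sub("^R", "", row_pools),
    column = as.integer(sub("^C", "", col_pools)),
    stringsAsFactors = FALSE
  )
  coords <- as_tibble(coords)
  key <- paste(map$bacs$plate, map$bacs$row, map$bacs$column, sep = "/")
  coords$bac_id <- map$bacs$bac_id[match(
    paste(coords$plate, coords$row, coords$column, sep = "/"), key)]
  coords
}

finalize_addresses <- function(out) {
  cols <- c("probe_id", "bac_id", "plate", "row", "column", "method", "resolution")
  if (length(out) == 0) {
    empty <- tibble(probe_id = character(), bac_id = character(),
                    plate = integer(), row = character(), column = integer(),
                    method = character(), resolution = character())
    return(empty)
  }
  bind_rows(out)[, cols]
}
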