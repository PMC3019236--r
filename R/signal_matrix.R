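#' Probe-by-pool hybridisation signal matrix
#'
#' Wraps a non-negative probe x pool intensity table together with the pool
#' layout and a normalisation state (`"raw"`, `"pool_normalised"` after the
#' per-pool median step, `"probe_normalised"` after the per-probe step).
#'
#' @param values A numeric matrix (probes x pools, rownames = probe ids) or a
#'   data frame with a `probe_id` column followed by one column per pool.
#' @param layout A [pool_layout()]; columns are reordered to match it.
#' @param state Normalisation state tag.
#' @return A `signal_matrix`: a tibble `probe_id` + pool columns, with the
#'   layout in attribute `"layout"` and the state in attribute `"state"`.
#' @export
signal_matrix <- function(values, layout, state = "raw") {
  if (is.matrix(values)) {
    df <- as_tibble(values, .name_repair = "minimal")
    df <- dplyr::bind_cols(tibble(probe_id = rownames(values) %||%
                                    paste0("probe_", seq_len(nrow(values)))), df)
  } else {
    df <- as_tibble(values)
  }
  if (!"probe_id" %in% names(df)) abort("signal matrix needs a probe_id column")
  pool_cols <- setdiff(names(df), "probe_id")
  missing <- setdiff(layout$pool_id, pool_cols)
  if (length(missing) > 0) {
    abort(paste0("missing pool column(s): ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(pool_cols, layout$pool_id)
  if (length(extra) > 0) {
    abort(paste0("unknown pool column(s): ", paste(extra, collapse = ", ")))
  }
  df <- df[, c("probe_id", layout$pool_id)]
  vals <- as.matrix(df[, layout$pool_id])
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-finite signal for probe ", df$probe_id[bad[1, 1]],
                 ", pool ", layout$pool_id[bad[1, 2]]))
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(paste0("negative signal for probe ", df$probe_id[neg[1, 1]],
                 ", pool ", layout$pool_id[neg[1, 2]]))
  }
  structure(df, layout = layout, state = state,
            class = c("signal_matrix", class(tibble())))
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x), " probes x ", ncol(x) - 1, " pools (",
      attr(x, "state"), ")\n", sep = "")
  NextMethod()
}

#' Extract the numeric matrix from a signal matrix
#' @param x A [signal_matrix()].
#' @param ... Unused.
#' @return Numeric matrix with probe ids as rownames.
#' @export
as.matrix.signal_matrix <- function(x, ...) {
  m <- as.matrix(as.data.frame(x[, setdiff(names(x), "probe_id")]))
  rownames(m) <- x$probe_id
  m
}

#' Read a probe-by-pool signal matrix from a tab-separated file
#'
#' The first column must be `probe_id`; the remaining columns must carry
#' exactly the pool ids of `layout` (any order; they are reordered to the
#' layout order). Negative or non-numeric cells are rejected with the probe
#' and pool named.
#'
#' @param path Path to a TSV file (`#` comments allowed).
#' @param layout A [pool_layout()].
#' @return A raw [signal_matrix()].
#' @export
read_signal_matrix <- function(path, layout) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  signal_matrix(df, layout, state = "raw")
}

#' Write a signal matrix to a tab-separated file
#' @param sm A [signal_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(sm, path) {
  readr::write_tsv(as_tibble(as.data.frame(sm)), path)
  invisible(path)
}

#' Two-step median normalisation of a signal matrix
#'
#' Step 1 makes pools comparable: every value is divided by the median of its
#' own pool, so each pool (column) median becomes 1. Step 2 makes probes
#' comparable: every value is then divided by the median of its own probe, so
#' each probe (row) median becomes exactly 1 while pool medians are left
#' essentially unchanged.
#'
#' @param sm A raw [signal_matrix()].
#' @return A `probe_normalised` [signal_matrix()].
#' @export
normalize_signals <- function(sm) {
  if (attr(sm, "state") != "raw") abort("normalize_signals expects a raw signal matrix")
  layout <- attr(sm, "layout")
  m <- as.matrix(sm)

  pool_med <- apply(m, 2, median)
  zero <- which(pool_med == 0)
  if (length(zero) > 0) {
    abort(paste0("zero median in pool(s): ", paste(colnames(m)[zero], collapse = ", ")))
  }
  m <- sweep(m, 2, pool_med, "/")

  probe_med <- apply(m, 1, median)
  zero <- which(probe_med == 0)
  if (length(zero) > 0) {
    abort(paste0("zero median for probe(s): ", paste(rownames(m)[zero], collapse = ", ")))
  }
  m <- sweep(m, 1, probe_med, "/")

  signal_matrix(m, layout, state = "probe_normalised")
}
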