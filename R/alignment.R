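#' Best local alignment between two nucleotide sequences
#'
#' Plain Smith-Waterman dynamic programming with linear gap costs
#' (match +1, mismatch -1, gap -2 by default). The best-scoring local
#' alignment is traced back and summarised by its number of matching
#' columns, total alignment columns (including gaps) and identity
#' (matches / columns).
#'
#' @param query,subject Nucleotide strings over `A`, `C`, `G`, `T`, `N`.
#'   `N` never counts as a match.
#' @param match,mismatch,gap Alignment scores.
#' @return A list: `score`, `matches`, `columns`, `identity`, and the
#'   half-open query/subject ranges of the alignment.
#' @export
local_align <- function(query, subject, match = 1, mismatch = -1, gap = -2) {
  q <- check_dna(query, "query")
  s <- check_dna(subject, "subject")
  n <- length(q)
  m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  jv <- seq_len(m)
  gap_ramp <- gap * jv
  # Row-wise recurrence. With linear gap costs the within-row (left)
  # dependency H[i,j] = max(A[j], H[i,j-1] + gap) is a running maximum:
  # H[i,j] = gap*j + cummax(A - gap*j), where A folds the diagonal, up and
  # zero cases.
  for (i in seq_len(n)) {
    prev <- H[i, ]
    subv <- ifelse(s == q[i] & q[i] != "N", match, mismatch)
    A <- pmax(prev[jv] + subv, prev[jv + 1L] + gap, 0)
    H[i + 1L, jv + 1L] <- gap_ramp + cummax(A - gap_ramp)
  }
  best <- max(H)
  hit <- which(H == best, arr.ind = TRUE)[1, ] # first optimum, row-major
  bi <- hit[[1]] - 1L
  bj <- hit[[2]] - 1L
  # Traceback by re-checking the recurrence (diag > up > left on ties).
  matches <- 0L
  columns <- 0L
  i <- bi + 1L
  j <- bj + 1L
  while (i > 1 && j > 1 && H[i, j] > 0) {
    val <- H[i, j]
    sub <- if (q[i - 1] == s[j - 1] && q[i - 1] != "N") match else mismatch
    columns <- columns + 1L
    if (val == H[i - 1, j - 1] + sub) {
      if (sub == match) matches <- matches + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (val == H[i - 1, j] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(
    score = best,
    matches = matches,
    columns = columns,
    identity = if (columns > 0) matches / columns else 0,
    query_start = i - 1L, query_end = bi,
    subject_start = j - 1L, subject_end = bj
  )
}

check_dna <- function(x, what) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    abort(paste0("non-ACGTN character(s) in ", what, ": ", paste(bad, collapse = ", ")))
  }
  chars
}

#' Flag probes matching a repeat library
#'
#' A probe is flagged as repeat-derived when its best local alignment to any
#' library sequence reaches at least `min_identity` identity over an aligned
#' span of at least `min_span` columns (defaults: 80% over 45 nt). Such
#' probes hybridise non-specifically across many pools and are removed
#' before locus building.
#'
#' @param probes A data frame with columns `probe_id` and `sequence`
#'   (60-mers), or a named character vector.
#' @param library A data frame with columns `repeat_id` and `sequence`, or a
#'   named character vector of repeat sequences.
#' @param min_identity Minimum identity of the best local alignment.
#' @param min_span Minimum aligned columns.
#' @param match,mismatch,gap Alignment scores, see [local_align()].
#' @return A tibble per probe: `probe_id`, `flagged`, `best_identity`,
#'   `best_span`, `best_repeat` (the repeat reaching the best qualifying or,
#'   failing that, best-scoring alignment).
#' @export
te_filter <- function(probes, library, min_identity = 0.80, min_span = 45,
                      match = 1, mismatch = -1, gap = -2) {
  probes <- as_sequence_table(probes, "probe_id")
  library <- as_sequence_table(library, "repeat_id")
  res <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    best <- list(score = -Inf, identity = 0, columns = 0L)
    best_rep <- NA_character_
    flagged <- FALSE
    for (j in seq_len(nrow(library))) {
      al <- local_align(probes$sequence[i], library$sequence[j],
                        match = match, mismatch = mismatch, gap = gap)
      qualifies <- al$identity >= min_identity && al$columns >= min_span
      if (qualifies && !flagged) {
        flagged <- TRUE
        best <- al
        best_rep <- library$repeat_id[j]
      } else if (qualifies == flagged && al$score > best$score) {
        best <- al
        best_rep <- library$repeat_id[j]
      }
    }
    res[[i]] <- tibble(
      probe_id = probes$probe_id[i],
      flagged = flagged,
      best_identity = best$identity,
      best_span = as.integer(best$columns),
      best_repeat = best_rep
    )
  }
  bind_rows(res)
}

as_sequence_table <- function(x, id_col) {
  if (is.character(x)) {
    out <- tibble(id = names(x) %||% paste0("seq_", seq_along(x)), sequence = unname(x))
    names(out)[1] <- id_col
    return(out)
  }
  x <- as_tibble(x)
  if (!all(c(id_col, "sequence") %in% names(x))) {
    abort(paste0("expected columns '", id_col, "' and 'sequence'"))
  }
  x[, c(id_col, "sequence")]
}
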