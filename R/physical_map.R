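#' Physical map of a chromosome as a tiled set of BAC clones
#'
#' A physical map holds the BAC clones of a minimal tiling path (MTP), their
#' well addresses in the pooled library (plate, row, column), their chromosome
#' coordinates, contig membership, the pairwise overlap relation derived from
#' coordinate intersection, and the assignment of contigs to deletion bins.
#' All coordinates are 0-based, half-open; megabases are `bp / 1e6` exactly.
#'
#' @param bacs A data frame with columns `bac_id`, `plate` (1-based integer or
#'   a label such as `"P03"`), `row` (letter), `column` (1-based integer),
#'   `contig_id` (`NA` for singletons, which receive a pseudo-contig of their
#'   own), `start_bp`, `end_bp` (may be `NA` when the contig is unplaced) and
#'   optionally `bin` (deletion-bin name, `NA` when unassigned).
#' @param bins Optional data frame describing the deletion bins in order from
#'   the short-arm telomere to the long-arm telomere, with columns `bin` and
#'   optionally `arm` (`"S"`, `"C"`, `"L"`), `start_bp`, `end_bp`. When absent,
#'   bins are taken in order of first appearance in `bacs`.
#'
#' @return An object of class `physical_map`: a list with tibbles `bacs`,
#'   `contigs`, `overlaps` (symmetric relation stored once per pair), and
#'   `bins`.
#' @export
physical_map <- function(bacs, bins = NULL) {
  bacs <- as_tibble(bacs)
  required <- c("bac_id", "plate", "row", "column", "contig_id", "start_bp", "end_bp")
  missing_cols <- setdiff(required, names(bacs))
  if (length(missing_cols) > 0) {
    abort(paste0("physical map is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"bin" %in% names(bacs)) bacs$bin <- NA_character_
  bacs$plate <- parse_plate(bacs$plate)
  bacs$row <- toupper(as.character(bacs$row))
  bacs$column <- as.integer(bacs$column)
  bacs$start_bp <- as.numeric(bacs$start_bp)
  bacs$end_bp <- as.numeric(bacs$end_bp)
  bacs$bin <- as.character(bacs$bin)

  bad <- which(!is.na(bacs$start_bp) & !is.na(bacs$end_bp) & bacs$end_bp <= bacs$start_bp)
  if (length(bad) > 0) {
    abort(paste0("end_bp <= start_bp for BAC(s) ", paste(bacs$bac_id[bad], collapse = ", "),
                 " (row ", paste(bad, collapse = ", "), ")"))
  }
  well <- paste(bacs$plate, bacs$row, bacs$column, sep = "/")
  dup <- well[duplicated(well)]
  if (length(dup) > 0) {
    offenders <- bacs$bac_id[well %in% dup]
    abort(paste0("duplicated well address ", dup[1], " shared by BACs: ",
                 paste(offenders, collapse = ", ")))
  }

  # Singletons carry their own pseudo-contig of one BAC.
  singleton <- is.na(bacs$contig_id) | bacs$contig_id == ""
  bacs$singleton <- singleton
  bacs$contig_id[singleton] <- paste0("singleton:", bacs$bac_id[singleton])

  # A contig's bin must be consistent across its BACs.
  bin_check <- bacs %>%
    group_by(.data$contig_id) %>%
    summarise(n_bins = dplyr::n_distinct(.data$bin, na.rm = FALSE), .groups = "drop") %>%
    filter(.data$n_bins > 1)
  if (nrow(bin_check) > 0) {
    abort(paste0("contig(s) with conflicting bin assignments: ",
                 paste(bin_check$contig_id, collapse = ", ")))
  }

  if (is.null(bins)) {
    seen <- unique(bacs$bin[!is.na(bacs$bin)])
    bins <- tibble(bin = seen, arm = NA_character_,
                   start_bp = NA_real_, end_bp = NA_real_)
  } else {
    bins <- as_tibble(bins)
    if (!"arm" %in% names(bins)) bins$arm <- NA_character_
    if (!"start_bp" %in% names(bins)) bins$start_bp <- NA_real_
    if (!"end_bp" %in% names(bins)) bins$end_bp <- NA_real_
    unknown <- setdiff(unique(bacs$bin[!is.na(bacs$bin)]), bins$bin)
    if (length(unknown) > 0) {
      lines <- which(bacs$bin %in% unknown)
      abort(paste0("unknown bin name(s) ", paste(unknown, collapse = ", "),
                   " at row(s) ", paste(lines, collapse = ", ")))
    }
  }

  contigs <- bacs %>%
    group_by(.data$contig_id) %>%
    summarise(
      n_bacs = dplyr::n(),
      start_bp = if (all(is.na(.data$start_bp))) NA_real_ else min(.data$start_bp, na.rm = TRUE),
      end_bp = if (all(is.na(.data$end_bp))) NA_real_ else max(.data$end_bp, na.rm = TRUE),
      bin = .data$bin[1],
      .groups = "drop"
    ) %>%
    mutate(length_bp = .data$end_bp - .data$start_bp) %>%
    arrange(.data$start_bp)

  overlaps <- derive_overlaps(bacs)

  structure(
    list(bacs = bacs, contigs = contigs, overlaps = overlaps, bins = bins),
    overlap_set = overlap_keys(overlaps),
    class = "physical_map"
  )
}

parse_plate <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  as.integer(gsub("[^0-9]", "", as.character(x)))
}

# Coordinate intersection within a contig, half-open: [a,b) and [c,d) overlap
# iff a < d and c < b; abutting intervals do not overlap.
derive_overlaps <- function(bacs) {
  placed <- bacs[!is.na(bacs$start_bp) & !is.na(bacs$end_bp), , drop = FALSE]
  if (nrow(placed) == 0) {
    return(tibble(bac1 = character(), bac2 = character()))
  }
  res <- placed %>%
    group_by(.data$contig_id) %>%
    dplyr::group_map(function(df, key) {
      df <- df[order(df$start_bp, df$end_bp), , drop = FALSE]
      n <- nrow(df)
      if (n < 2) return(NULL)
      out <- vector("list", n)
      for (i in seq_len(n - 1)) {
        j <- i + 1L
        hits <- character(0)
        while (j <= n && df$start_bp[j] < df$end_bp[i]) {
          hits <- c(hits, df$bac_id[j])
          j <- j + 1L
        }
        if (length(hits) > 0) out[[i]] <- tibble(bac1 = df$bac_id[i], bac2 = hits)
      }
      bind_rows(out)
    })
  out <- bind_rows(res)
  if (nrow(out) == 0) tibble(bac1 = character(), bac2 = character()) else out
}

overlap_keys <- function(overlaps) {
  c(paste(overlaps$bac1, overlaps$bac2, sep = "\r"),
    paste(overlaps$bac2, overlaps$bac1, sep = "\r"))
}

#' Do two BACs overlap on the physical map?
#'
#' @param map A [physical_map()].
#' @param a,b Character vectors of BAC ids (recycled to common length).
#' @return Logical vector; `TRUE` where the pair overlaps within a contig.
#' @export
bacs_overlap <- function(map, a, b) {
  paste(a, b, sep = "\r") %in% attr(map, "overlap_set")
}

#' Are a set of BACs mutually overlapping?
#' @param map A [physical_map()].
#' @param ids Character vector of BAC ids.
#' @return `TRUE` iff every pair overlaps (vacuously `TRUE` for a single id).
#' @export
bacs_mutually_overlap <- function(map, ids) {
  if (length(ids) < 2) return(TRUE)
  prs <- combn(ids, 2)
  all(bacs_overlap(map, prs[1, ], prs[2, ]))
}

#' @export
print.physical_map <- function(x, ...) {
  cat("<physical_map> ", nrow(x$bacs), " BACs in ", nrow(x$contigs), " contigs; ",
      nrow(x$overlaps), " overlapping pairs; ", nrow(x$bins), " bins\n", sep = "")
  invisible(x)
}

#' Read a physical map from a tab-separated file
#'
#' The file must have a header with columns `bac_id`, `plate`, `row`,
#' `column`, `contig_id`, `start_bp`, `end_bp`, `bin`; `#` starts a comment.
#' Empty fields are `NA`. Errors report the offending line.
#'
#' @param path Path to a TSV file.
#' @param bins Optional bin table passed on to [physical_map()].
#' @return A [physical_map()].
#' @export
read_physical_map <- function(path, bins = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  for (col in c("column", "start_bp", "end_bp")) {
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  physical_map(df, bins = bins)
}

#' Write a physical map back to a tab-separated file
#'
#' Writes the BAC table in the same column layout [read_physical_map()]
#' expects, so that read/write round-trips are content-identical.
#'
#' @param map A [physical_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physical_map <- function(map, path) {
  out <- map$bacs
  out$contig_id[out$singleton] <- NA_character_
  out <- out[, c("bac_id", "plate", "row", "column", "contig_id", "start_bp", "end_bp", "bin")]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Pool layout of a three-dimensional BAC library
#'
#' Expands the well addresses of a physical map into the plate, row and
#' column pools of the screening design. Every BAC belongs to exactly one
#' pool per axis.
#'
#' @param map A [physical_map()].
#' @param n_plates,n_rows,n_cols Pool geometry. Defaults infer the smallest
#'   geometry containing all well addresses.
#' @return A `pool_layout` tibble with columns `pool_id`, `axis`
#'   (`"plate"`, `"row"`, `"column"`), `n_bacs` and a list column `members`;
#'   the geometry is kept in attribute `"geometry"`.
#' @export
pool_layout <- function(map, n_plates = NULL, n_rows = NULL, n_cols = NULL) {
  bacs <- map$bacs
  n_plates <- n_plates %||% max(bacs$plate)
  n_rows <- n_rows %||% max(match(bacs$row, LETTERS))
  n_cols <- n_cols %||% max(bacs$column)
  plate_ids <- sprintf("P%02d", seq_len(n_plates))
  row_ids <- paste0("R", LETTERS[seq_len(n_rows)])
  col_ids <- sprintf("C%02d", seq_len(n_cols))
  pools <- tibble(
    pool_id = c(plate_ids, row_ids, col_ids),
    axis = rep(c("plate", "row", "column"), c(n_plates, n_rows, n_cols))
  )
  bac_pools <- tibble(
    bac_id = rep(bacs$bac_id, 3),
    pool_id = c(sprintf("P%02d", bacs$plate), paste0("R", bacs$row),
                sprintf("C%02d", bacs$column))
  )
  members <- split(bac_pools$bac_id, factor(bac_pools$pool_id, levels = pools$pool_id))
  pools$members <- unname(members)
  pools$n_bacs <- lengths(pools$members)
  structure(pools,
            geometry = c(plate = n_plates, row = n_rows, column = n_cols),
            class = c("pool_layout", class(pools)))
}

#' Pools containing a given BAC
#' @param layout A [pool_layout()].
#' @param bac_id A single BAC id.
#' @return Character vector of three pool ids (plate, row, column).
#' @export
pools_of_bac <- function(layout, bac_id) {
  layout$pool_id[map_lgl(layout$members, function(m) bac_id %in% m)]
}

#' Well address implied by one pool per axis
#' @param pools Character vector of pool ids, one per axis.
#' @return A list with `plate`, `row`, `column` components.
#' @keywords internal
parse_pools <- function(pools) {
  list(
    plate = as.integer(sub("^P", "", grep("^P", pools, value = TRUE))),
    row = sub("^R", "", grep("^R", pools, value = TRUE)),
    column = as.integer(sub("^C", "", grep("^C", pools, value = TRUE)))
  )
}

#' Find the BAC sitting at a well address, if any
#' @param map A [physical_map()].
#' @param plate,row,column Scalar well coordinates.
#' @return The BAC id, or `NA_character_` when the well is empty.
#' @export
bac_at_well <- function(map, plate, row, column) {
  hit <- map$bacs$bac_id[map$bacs$plate == plate & map$bacs$row == row &
                           map$bacs$column == column]
  if (length(hit) == 0) NA_character_ else hit[1]
}
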