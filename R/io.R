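#' Readers and writers for the package's tabular formats
#'
#' Plain-TSV dialects: pair tables (`chrom1, pos1, strand1, chrom2, pos2,
#' strand2`), cut-site tables (`chrom, pos`, 0-based), contact tables
#' (`bait, chrom, frag_idx, start, end, count`, plus optional `norm_count`
#' and `masked`). BED is 0-based half-open; BEDPE carries the standard ten
#' columns. Writing then reading a valid file is the identity; malformed
#' rows are reported with their row number.
#'
#' @param path File path.
#' @name c3c_io
NULL

#' @rdname c3c_io
#' @export
read_pairs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom1 = "c", pos1 = "d", strand1 = "c",
                         chrom2 = "c", pos2 = "d", strand2 = "c"))
  .require_pair_cols(x)
  bad <- which(!x$strand1 %in% c("+", "-") | !x$strand2 %in% c("+", "-"))
  if (length(bad)) abort(paste0("invalid strand at row ", bad[1]))
  x
}

#' @rdname c3c_io
#' @param pairs Pair tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname c3c_io
#' @export
read_sites <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", pos = "d"))
  bad <- which(is.na(x$pos) | x$pos < 0)
  if (length(bad)) abort(paste0("invalid cut-site position at row ", bad[1]))
  x
}

#' @rdname c3c_io
#' @param sites Cut-site tibble (`chrom`, `pos`).
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites[, c("chrom", "pos")], path)
  invisible(path)
}

#' @rdname c3c_io
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(x) < 3) abort("BED needs at least 3 columns")
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(paste0("malformed BED interval at row ", bad[1], ": start >= end"))
  }
  x
}

#' @rdname c3c_io
#' @param intervals Interval tibble with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname c3c_io
#' @export
read_contacts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("bait", "chrom", "frag_idx", "start", "end", "count")
  if (!all(req %in% names(x))) {
    abort(paste0("contacts TSV must have columns ", paste(req, collapse = ", ")))
  }
  bad <- which(x$start >= x$end | x$count < 0 | x$count != floor(x$count))
  if (length(bad)) abort(paste0("malformed contacts row ", bad[1]))
  x
}

#' @rdname c3c_io
#' @param contacts Contacts tibble or `contact_table`.
#' @export
write_contacts <- function(contacts, path) {
  x <- if (inherits(contacts, "contact_table")) contacts$counts else contacts
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname c3c_io
#' @param calls Tibble of significant bait-fragment rows (`bait`, `chrom`,
#'   `start`, `end`, `count`, `p`) joined with bait intervals.
#' @param baits Bait table providing the anchor interval of each bait.
#' @export
write_bedpe <- function(calls, baits, path) {
  b <- baits[match(calls$bait, baits$name), ]
  out <- tibble(
    chrom1 = b$chrom, start1 = b$start, end1 = b$end,
    chrom2 = calls$chrom, start2 = calls$start, end2 = calls$end,
    name = calls$bait, score = calls$count,
    strand1 = ".", strand2 = "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname c3c_io
#' @export
read_bedpe <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(x) < 6) abort("BEDPE needs at least 6 columns")
  names(x)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(x) >= 10) names(x)[7:10] <- c("name", "score", "strand1", "strand2")
  bad <- which(x$start1 >= x$end1 | x$start2 >= x$end2)
  if (length(bad)) abort(paste0("malformed BEDPE interval at row ", bad[1]))
  x
}

#' @rdname c3c_io
#' @param stats One-row stats tibble or named list.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(as.list(stats), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname c3c_io
#' @export
read_stats_json <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Export a bait-by-fragment contact matrix
#'
#' Rows are baits in locus order (the bait-table order), columns are the
#' fragments of one chromosome in coordinate order; cells carry normalized
#' counts, masked cells carry the sentinel `NA` (never zero), and cells
#' without observations are 0.
#'
#' @param masked_contacts Normalized contacts tibble with a `masked` column
#'   (see [mask_bait_proximal()]).
#' @param baits Bait table ordering the rows.
#' @param map A [restriction_map()].
#' @param chrom Chromosome whose fragments form the columns.
#' @param path Optional TSV output path.
#' @param exclusion_bp Optional bait-proximal exclusion half-width; when
#'   given, every cell inside the window is masked (including zero cells),
#'   otherwise only flagged observed cells are.
#' @return Wide tibble: `bait` column plus one column per fragment
#'   (`<start>_<end>` labels), invisibly when `path` is given.
#' @export
export_heatmap <- function(masked_contacts, baits, map, chrom, path = NULL,
                           exclusion_bp = NULL) {
  frs <- fragments(map, chrom)
  bset <- baits$name[baits$name %in% unique(masked_contacts$bait)]
  if (!length(bset)) warning("empty contact set; empty matrix", call. = FALSE)
  cc <- masked_contacts[masked_contacts$chrom == chrom, ]
  val_col <- if ("norm_count" %in% names(cc)) "norm_count" else "count"
  mat <- matrix(0, nrow = length(bset), ncol = nrow(frs),
                dimnames = list(bset, paste0(frs$start, "_", frs$end)))
  ri <- match(cc$bait, bset)
  ci <- match(cc$frag_idx, frs$frag_idx)
  ok <- !is.na(ri) & !is.na(ci)
  mat[cbind(ri[ok], ci[ok])] <- cc[[val_col]][ok]
  if ("masked" %in% names(cc)) {
    mk <- ok & cc$masked
    mat[cbind(ri[mk], ci[mk])] <- NA_real_
  }
  if (!is.null(exclusion_bp)) {
    for (i in seq_along(bset)) {
      b <- baits[baits$name == bset[i], ]
      if (b$chrom != chrom) next
      win <- frs$start <= b$site_pos + exclusion_bp &
        frs$end > b$site_pos - exclusion_bp
      mat[i, win] <- NA_real_
    }
  }
  out <- bind_cols(tibble(bait = bset), as_tibble(mat))
  if (!is.null(path)) {
    readr::write_tsv(out, path, na = "NA")
    return(invisible(out))
  }
  out
}
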