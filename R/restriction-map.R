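#' Locate restriction recognition sites in a sequence
#'
#' Finds every exact occurrence of a restriction-enzyme recognition motif
#' (EcoRI `GAATTC` by default) in a nucleotide sequence. Matching is
#' case-insensitive (soft-masked lowercase sequence is searched too),
#' overlapping occurrences are all reported, and `N` bases never match.
#'
#' The returned coordinate is the 0-based start of the recognition site,
#' not the nick position within it; all fragment arithmetic in the package
#' is anchored at recognition-site starts.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (either case). An empty string yields an empty result.
#' @param motif Recognition motif, `A`/`C`/`G`/`T` only.
#' @return Integer vector of 0-based motif start coordinates, ascending.
#' @examples
#' digest("TTGAATTCCCGAATTCAA")
#' @export
digest <- function(sequence, motif = "GAATTC") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single character string")
  }
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    abort("invalid motif: must be non-empty and contain only A, C, G, T")
  }
  if (!nzchar(sequence)) {
    return(integer(0))
  }
  subject <- Biostrings::DNAString(toupper(sequence))
  hits <- Biostrings::matchPattern(motif, subject, fixed = TRUE)
  as.integer(BiocGenerics::start(hits)) - 1L
}

#' Build a restriction map from cut sites and chromosome lengths
#'
#' A restriction map holds, per chromosome, the sorted 0-based cut-site
#' coordinates and the chromosome length. The half-open fragments between
#' consecutive sites tile each chromosome exactly once (see [fragments()]).
#'
#' @param sites Data frame with columns `chrom` and `pos` (0-based cut-site
#'   start coordinates).
#' @param chrom_lengths Either a data frame with columns `chrom` and `length`,
#'   or a named numeric vector of chromosome lengths in bp.
#' @param motif_width Width of the recognition site, used to validate that
#'   every site fits inside its chromosome.
#' @return An object of class `restriction_map`.
#' @seealso [restriction_map_from_seqs()], [fragments()], [design_baits()]
#' @export
restriction_map <- function(sites, chrom_lengths, motif_width = 6L) {
  sites <- as_tibble(sites)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    abort("`sites` must have columns `chrom` and `pos`")
  }
  if (is.data.frame(chrom_lengths)) {
    lens <- setNames(as.numeric(chrom_lengths$length), chrom_lengths$chrom)
  } else {
    if (is.null(names(chrom_lengths))) abort("`chrom_lengths` must be named")
    lens <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  missing_chr <- setdiff(unique(sites$chrom), names(lens))
  if (length(missing_chr)) {
    abort(paste0("sites on chromosomes without a length: ",
                 paste(missing_chr, collapse = ", ")))
  }
  sites <- sites |>
    transmute(chrom = as.character(chrom), pos = as.numeric(pos)) |>
    arrange(chrom, pos)
  by_chrom <- split(sites$pos, sites$chrom)
  for (chr in names(by_chrom)) {
    s <- by_chrom[[chr]]
    if (anyDuplicated(s)) abort(paste0("duplicated cut sites on ", chr))
    if (any(s < 0) || any(s > lens[[chr]] - motif_width)) {
      abort(paste0("cut site out of range on ", chr,
                   " (need 0 <= pos <= length - ", motif_width, ")"))
    }
  }
  structure(
    list(sites = sites, lengths = lens, motif_width = as.integer(motif_width)),
    class = "restriction_map"
  )
}

#' Digest a set of sequences into a restriction map
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param motif Recognition motif passed to [digest()].
#' @return A `restriction_map`.
#' @export
restriction_map_from_seqs <- function(seqs, motif = "GAATTC") {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("`seqs` must be a named character vector")
  }
  hits <- purrr::imap(seqs, function(s, nm) tibble(chrom = nm, pos = digest(s, motif)))
  restriction_map(
    bind_rows(hits),
    setNames(nchar(seqs), names(seqs)),
    motif_width = nchar(motif)
  )
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("<restriction_map> ", length(x$lengths), " chromosome(s), ",
      nrow(x$sites), " cut sites, motif width ", x$motif_width, "\n", sep = "")
  invisible(x)
}

.map_sites <- function(map, chr) {
  map$sites$pos[map$sites$chrom == chr]
}

.check_chrom <- function(map, chr) {
  bad <- setdiff(unique(chr), names(map$lengths))
  if (length(bad)) {
    abort(paste0("unknown chromosome(s): ", paste(bad, collapse = ", ")))
  }
}

#' Restriction fragments induced by a map
#'
#' Fragments are half-open intervals `[prev_site, next_site)` delimited at
#' recognition-site starts, padded with `[0, first)` and `[last, length)`;
#' empty leading/trailing intervals (a site at coordinate 0) are dropped.
#' Together they partition each chromosome.
#'
#' @param map A [restriction_map()].
#' @param chrom Optional chromosome name(s); default all.
#' @return Tibble with columns `chrom`, `frag_idx` (1-based per chromosome),
#'   `start`, `end` (0-based half-open).
#' @export
fragments <- function(map, chrom = NULL) {
  stopifnot(inherits(map, "restriction_map"))
  chrs <- chrom %||% names(map$lengths)
  .check_chrom(map, chrs)
  purrr::map_dfr(chrs, function(chr) {
    bounds <- unique(c(0, .map_sites(map, chr), map$lengths[[chr]]))
    tibble(
      chrom = chr,
      frag_idx = seq_len(length(bounds) - 1L),
      start = bounds[-length(bounds)],
      end = bounds[-1]
    )
  })
}

#' Design capture bait regions around in-locus cut sites
#'
#' For every cut site inside each target locus, two half-open probe regions
#' are emitted: the upstream flank `[site - flank, site)` (`U`) and the
#' downstream flank `[site, site + flank)` (`D`), truncated at chromosome
#' bounds. Sites are numbered 1..n in coordinate order within each locus and
#' regions are named `<prefix>E<index><side>` (e.g. `BE7U`); the prefix is
#' the locus letter (`A` for the first locus on a chromosome, `B` for the
#' second, empty when the locus is alone on its chromosome).
#'
#' @param map A [restriction_map()].
#' @param loci Data frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open) and `prefix`.
#' @param flank Flank width in bp on each side of the cut site.
#' @return Tibble with columns `name`, `locus`, `chrom`, `site_index`,
#'   `side`, `start`, `end`, `site_pos`, `flank`. A locus containing no cut
#'   sites raises a warning and contributes no baits.
#' @export
design_baits <- function(map, loci, flank = 250) {
  stopifnot(inherits(map, "restriction_map"))
  loci <- as_tibble(loci)
  req <- c("name", "chrom", "start", "end", "prefix")
  if (!all(req %in% names(loci))) {
    abort(paste0("`loci` must have columns ", paste(req, collapse = ", ")))
  }
  if (any(loci$start >= loci$end)) abort("locus with start >= end")
  if (flank <= 0) abort("`flank` must be positive")
  .check_chrom(map, loci$chrom)
  out <- purrr::pmap_dfr(loci, function(name, chrom, start, end, prefix, ...) {
    s <- .map_sites(map, chrom)
    s <- s[s >= start & s < end]
    if (!length(s)) {
      warning("locus '", name, "' contains no cut sites; no baits designed",
              call. = FALSE)
      return(tibble())
    }
    L <- map$lengths[[chrom]]
    idx <- seq_along(s)
    tibble(
      locus = name, chrom = chrom, site_index = rep(idx, each = 2L),
      side = rep(c("U", "D"), length(s)),
      start = as.numeric(rbind(pmax(s - flank, 0), s)),
      end = as.numeric(rbind(s, pmin(s + flank, L))),
      site_pos = rep(s, each = 2L),
      name = paste0(prefix, "E", rep(idx, each = 2L), rep(c("U", "D"), length(s)))
    )
  })
  if (!nrow(out)) return(out)
  out |>
    filter(end > start) |>
    mutate(flank = flank) |>
    select(name, locus, chrom, site_index, side, start, end, site_pos, flank)
}

#' Parse a bait name back into its components
#'
#' Inverts the `<prefix>E<index><side>` naming convention used by
#' [design_baits()].
#'
#' @param name Character vector of bait names such as `"BE7U"` or `"E10D"`.
#' @return Tibble with columns `name`, `prefix`, `site_index`, `side`.
#' @export
parse_bait_name <- function(name) {
  m <- stringr::str_match(name, "^([A-Za-z]*)E([0-9]+)([UD])$")
  if (anyNA(m[, 1])) {
    abort(paste0("unparseable bait name(s): ",
                 paste(name[is.na(m[, 1])], collapse = ", ")))
  }
  tibble(
    name = name,
    prefix = m[, 2],
    site_index = as.integer(m[, 3]),
    side = m[, 4]
  )
}
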