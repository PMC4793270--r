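#' Assign aligned coordinates to restriction fragments
#'
#' Each coordinate is assigned to the unique half-open fragment containing
#' it, together with its distance to the nearest cut site (chromosome ends
#' are not cut sites; a chromosome with no sites gives distance `Inf`).
#'
#' @param map A [restriction_map()].
#' @param chrom,pos Parallel vectors of chromosome names and 0-based
#'   coordinates; positions must satisfy `0 <= pos < chromosome length`.
#' @return Tibble with columns `chrom`, `pos`, `frag_idx`, `dist`.
#' @export
assign_end <- function(map, chrom, pos) {
  stopifnot(inherits(map, "restriction_map"), length(chrom) == length(pos))
  .check_chrom(map, chrom)
  frs <- fragments(map)
  out <- tibble(chrom = as.character(chrom), pos = as.numeric(pos),
                frag_idx = NA_integer_, dist = NA_real_)
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr)
    p <- out$pos[i]
    L <- map$lengths[[chr]]
    if (any(p < 0 | p >= L)) {
      abort(paste0("coordinate out of range on ", chr, " (need 0 <= pos < ", L, ")"))
    }
    fr <- frs[frs$chrom == chr, ]
    out$frag_idx[i] <- findInterval(p, fr$start)
    s <- .map_sites(map, chr)
    if (length(s)) {
      j <- findInterval(p, s)
      dl <- ifelse(j >= 1, p - s[pmax(j, 1L)], Inf)
      dr <- ifelse(j < length(s), s[pmin(j + 1L, length(s))] - p, Inf)
      out$dist[i] <- pmin(dl, dr)
    } else {
      out$dist[i] <- Inf
    }
  }
  out
}

# Anchor each end to its bait region, if any.
# An end is anchorable iff it lies inside a target locus AND inside the
# half-open U/D flank interval of the nearest cut site within that locus.
# Ties (coordinate exactly on a site, or equidistant between two sites)
# resolve to the left site's D flank.
.anchor_ends <- function(map, baits, loci, chrom, pos, flank = 250) {
  n <- length(pos)
  res <- tibble(bait = rep(NA_character_, n), site_pos = NA_real_,
                dist = NA_real_)
  if (!nrow(loci)) return(res)
  for (k in seq_len(nrow(loci))) {
    lc <- loci$chrom[k]
    in_loc <- which(chrom == lc & pos >= loci$start[k] & pos < loci$end[k])
    if (!length(in_loc)) next
    s <- .map_sites(map, lc)
    s <- s[s >= loci$start[k] & s < loci$end[k]]
    if (!length(s)) next
    p <- pos[in_loc]
    j <- findInterval(p, s)
    dl <- ifelse(j >= 1, p - s[pmax(j, 1L)], Inf)
    dr <- ifelse(j < length(s), s[pmin(j + 1L, length(s))] - p, Inf)
    use_left <- dl <= dr
    site <- ifelse(use_left, s[pmax(j, 1L)], s[pmin(j + 1L, length(s))])
    side <- ifelse(use_left, "D", "U")
    ok <- ifelse(use_left, dl < flank, dr <= flank)
    bk <- baits[baits$chrom == lc, c("name", "site_pos", "side")]
    key <- paste(site, side)
    hit <- match(key, paste(bk$site_pos, bk$side))
    ok <- ok & !is.na(hit)
    idx <- in_loc[ok]
    res$bait[idx] <- bk$name[hit[ok]]
    res$site_pos[idx] <- site[ok]
    res$dist[idx] <- pmin(dl, dr)[ok]
  }
  res
}

.require_pair_cols <- function(pairs) {
  req <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(req %in% names(pairs))) {
    abort(paste0("pair table must have columns ", paste(req, collapse = ", ")))
  }
}

#' Put read-pair ends in canonical order
#'
#' Ends are stored in lexicographic order by `(chrom, pos, strand)` so that
#' order-swapped PCR duplicates compare equal.
#'
#' @param pairs Data frame with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (plus optional `mapped1`, `mapped2`).
#' @return The same tibble with ends swapped into canonical order.
#' @export
canonical_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  .require_pair_cols(pairs)
  swap <- (pairs$chrom1 > pairs$chrom2) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 == pairs$pos2 &
       pairs$strand1 > pairs$strand2)
  cols1 <- c("chrom1", "pos1", "strand1")
  cols2 <- c("chrom2", "pos2", "strand2")
  if ("mapped1" %in% names(pairs)) {
    cols1 <- c(cols1, "mapped1")
    cols2 <- c(cols2, "mapped2")
  }
  tmp <- pairs[swap, cols1]
  pairs[swap, cols1] <- pairs[swap, cols2]
  pairs[swap, cols2] <- tmp
  pairs
}

#' Flag coordinate-identical PCR duplicates
#'
#' After canonical end ordering, the first occurrence of each
#' `(chrom1, pos1, strand1, chrom2, pos2, strand2)` tuple is retained and
#' every later identical tuple is flagged as a duplicate. Coordinates plus
#' strands stand proxy for sequence identity. The operation is idempotent.
#'
#' @inheritParams canonical_pairs
#' @return The canonicalized tibble with a logical `duplicate` column.
#' @export
dedup_pairs <- function(pairs) {
  pairs <- canonical_pairs(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  pairs$duplicate <- duplicated(key)
  pairs
}

#' Classify read pairs as on-target cis, on-target trans, or off-target
#'
#' A pair is on-target (informative) iff at least one end lies inside a
#' target locus within the flank of a locus cut site; that end's anchor is
#' the U or D probe region containing it. An on-target pair is cis when the
#' other end maps to the same chromosome and trans otherwise. A pair whose
#' both ends are bait-proximal anchors to both baits.
#'
#' @param pairs Canonically ordered, fully mapped pair table.
#' @param map A [restriction_map()].
#' @param baits Bait table from [design_baits()].
#' @param loci Target locus table.
#' @param flank Maximum distance (bp) from an in-locus cut site.
#' @return The tibble with added columns `bait1`, `bait2` (anchor bait names
#'   or `NA`), `site1`, `site2` (anchor cut sites) and `category`.
#' @export
classify_pairs <- function(pairs, map, baits, loci, flank = 250) {
  pairs <- as_tibble(pairs)
  .require_pair_cols(pairs)
  a1 <- .anchor_ends(map, baits, loci, pairs$chrom1, pairs$pos1, flank)
  a2 <- .anchor_ends(map, baits, loci, pairs$chrom2, pairs$pos2, flank)
  pairs$bait1 <- a1$bait
  pairs$bait2 <- a2$bait
  pairs$site1 <- a1$site_pos
  pairs$site2 <- a2$site_pos
  on <- !is.na(a1$bait) | !is.na(a2$bait)
  pairs$category <- ifelse(!on, "off_target",
                           ifelse(pairs$chrom1 == pairs$chrom2,
                                  "on_target_cis", "on_target_trans"))
  pairs
}

#' Extract per-bait contact profiles from aligned read pairs
#'
#' Runs the full filtering cascade: drop pairs with an unmapped end, remove
#' coordinate duplicates, classify the remainder, and aggregate on-target
#' pairs into counts per (bait, partner fragment). Every input pair lands in
#' exactly one of the accounting categories (unmapped, duplicate,
#' off-target, on-target cis, on-target trans).
#'
#' @inheritParams classify_pairs
#' @return A `contact_table`: list with `counts` (tibble `bait`, `chrom`,
#'   `frag_idx`, `start`, `end`, `count`) and `stats` (one-row accounting
#'   tibble). `tidy()` returns the counts, `glance()` the stats.
#' @export
extract_contacts <- function(pairs, map, baits, loci, flank = 250) {
  pairs <- as_tibble(pairs)
  .require_pair_cols(pairs)
  n_raw <- nrow(pairs)
  if (!"mapped1" %in% names(pairs)) pairs$mapped1 <- TRUE
  if (!"mapped2" %in% names(pairs)) pairs$mapped2 <- TRUE
  mapped <- pairs$mapped1 & pairs$mapped2
  n_unmapped <- sum(!mapped)
  pairs <- pairs[mapped, ]
  pairs <- dedup_pairs(pairs)
  n_dup <- sum(pairs$duplicate)
  pairs <- pairs[!pairs$duplicate, ]
  cls <- classify_pairs(pairs, map, baits, loci, flank)
  n_off <- sum(cls$category == "off_target")
  n_cis <- sum(cls$category == "on_target_cis")
  n_trans <- sum(cls$category == "on_target_trans")

  long <- bind_rows(
    cls |> filter(!is.na(bait1)) |>
      transmute(bait = bait1, chrom = chrom2, pos = pos2),
    cls |> filter(!is.na(bait2)) |>
      transmute(bait = bait2, chrom = chrom1, pos = pos1)
  )
  if (nrow(long)) {
    asn <- assign_end(map, long$chrom, long$pos)
    counts <- long |>
      mutate(frag_idx = asn$frag_idx) |>
      count(bait, chrom, frag_idx, name = "count") |>
      left_join(fragments(map), by = c("chrom", "frag_idx")) |>
      select(bait, chrom, frag_idx, start, end, count) |>
      arrange(bait, chrom, frag_idx)
  } else {
    counts <- tibble(bait = character(), chrom = character(),
                     frag_idx = integer(), start = numeric(),
                     end = numeric(), count = integer())
  }
  n_mapped <- n_raw - n_unmapped
  n_on <- n_cis + n_trans
  stats <- tibble(
    raw_pairs = n_raw,
    unmapped = n_unmapped,
    mapped = n_mapped,
    duplicates = n_dup,
    off_target = n_off,
    on_target = n_on,
    cis = n_cis,
    trans = n_trans,
    pct_on_target = if (n_mapped - n_dup > 0) 100 * n_on / (n_mapped - n_dup) else NA_real_,
    pct_cis = if (n_on > 0) 100 * n_cis / n_on else NA_real_,
    pct_trans = if (n_on > 0) 100 * n_trans / n_on else NA_real_
  )
  structure(list(counts = counts, stats = stats), class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat("<contact_table> ", nrow(x$counts), " (bait, fragment) cells, ",
      sum(x$counts$count), " on-target pairs\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' @rdname extract_contacts
#' @param x A `contact_table`.
#' @param ... Unused.
#' @export
tidy.contact_table <- function(x, ...) x$counts

#' @rdname extract_contacts
#' @export
glance.contact_table <- function(x, ...) x$stats

#' Genomic distances of cis on-target ligation events
#'
#' One distance per cis pair: from the anchor's cut site to the partner end.
#' A pair anchored at both ends contributes a single distance (from its
#' first anchor; both anchor-to-partner distances of such a pair agree to
#' within the flank width, and counting both would double short-range mass
#' and bias a decay fit). Used to examine the ligation-frequency distance
#' decay.
#'
#' @inheritParams classify_pairs
#' @return Numeric vector of distances in bp.
#' @export
pair_distances <- function(pairs, map, baits, loci, flank = 250) {
  cls <- classify_pairs(canonical_pairs(pairs), map, baits, loci, flank)
  cls <- cls[cls$category == "on_target_cis", ]
  ifelse(!is.na(cls$bait1),
         abs(cls$pos2 - cls$site1),
         abs(cls$pos1 - cls$site2))
}

#' Fit a power-law exponent to a ligation distance-decay profile
#'
#' Bins distances into logarithmically spaced bins, converts counts to a
#' per-bp density, and fits `log(density) ~ log(distance)` by least squares.
#' For contact frequencies decaying as `d^-alpha` the fitted slope
#' approximates `-alpha`.
#'
#' @param distances Numeric vector of ligation distances in bp.
#' @param dmin,dmax Distance range to fit over.
#' @param n_bins Number of logarithmic bins.
#' @return List with `slope` and the binned `profile` tibble.
#' @export
fit_decay <- function(distances, dmin = 5e3, dmax = 2e5, n_bins = 15) {
  d <- distances[distances >= dmin & distances < dmax]
  if (length(d) < 100) abort("too few distances in range to fit a decay slope")
  brk <- exp(seq(log(dmin), log(dmax), length.out = n_bins + 1))
  bin <- cut(d, brk, include.lowest = TRUE)
  cnt <- as.numeric(table(bin))
  width <- diff(brk)
  mid <- sqrt(brk[-1] * brk[-length(brk)])
  keep <- cnt > 0
  profile <- tibble(distance = mid[keep], density = (cnt / width)[keep])
  fit <- lm(log(density) ~ log(distance), data = profile)
  list(slope = unname(stats::coef(fit)[2]), profile = profile)
}
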