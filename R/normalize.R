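#' Probe capture-efficiency QC and filtering
#'
#' Capture efficiency is proxied by each probe's raw on-target read total
#' (designed probes with no reads count as zero). The `floor(pct/100 * P)`
#' probes with the smallest totals are removed as low-efficiency, ties
#' broken by bait name ascending (lexicographically earlier names removed
#' first). Probes overlapping an optional repeat-region track are removed
#' regardless of counts. Scaling factors for the retained probes are
#' `median(retained totals) / probe total`, with the median recomputed on
#' the retained set (the usual average-of-middle-two convention).
#'
#' @param contacts A `contact_table` from [extract_contacts()], or its
#'   counts tibble.
#' @param baits Bait design table; defines the full probe set including
#'   probes with zero reads.
#' @param pct Percentile of probes to drop as low-efficiency.
#' @param repeats Optional tibble of repeat intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @return Tibble with columns `bait`, `raw_total`, `factor` (NA for removed
#'   probes) and `status` (`retained`, `removed_low_efficiency`,
#'   `removed_repeat`).
#' @export
probe_qc <- function(contacts, baits, pct = 22, repeats = NULL) {
  counts <- if (inherits(contacts, "contact_table")) contacts$counts else as_tibble(contacts)
  if (pct < 0 || pct >= 100) abort("`pct` must be in [0, 100)")
  totals <- counts |>
    group_by(bait) |>
    summarise(raw_total = sum(count), .groups = "drop")
  qc <- baits |>
    select(name, chrom, start, end) |>
    left_join(totals, by = c(name = "bait")) |>
    mutate(raw_total = coalesce(raw_total, 0L)) |>
    rename(bait = name)
  P <- nrow(qc)
  if (P < 1) abort("no probes to filter")
  n_rm <- floor(pct / 100 * P)
  ord <- order(qc$raw_total, qc$bait)
  qc$status <- "retained"
  if (n_rm > 0) qc$status[ord[seq_len(n_rm)]] <- "removed_low_efficiency"
  if (!is.null(repeats) && nrow(repeats)) {
    hits <- .overlap_any(qc, repeats)
    qc$status[hits] <- "removed_repeat"
  }
  zero_keep <- qc$status == "retained" & qc$raw_total == 0
  if (any(zero_keep)) {
    warning(sum(zero_keep), " retained probe(s) with zero total removed before ",
            "factor computation", call. = FALSE)
    qc$status[zero_keep] <- "removed_low_efficiency"
  }
  if (!any(qc$status == "retained")) {
    warning("all probes removed; no retained probe to normalize against",
            call. = FALSE)
    qc$factor <- NA_real_
  } else {
    med <- median(qc$raw_total[qc$status == "retained"])
    qc$factor <- ifelse(qc$status == "retained", med / qc$raw_total, NA_real_)
  }
  qc |> select(bait, raw_total, factor, status)
}

# any-overlap of qc probe intervals with a set of intervals, same chromosome
.overlap_any <- function(qc, intervals) {
  res <- logical(nrow(qc))
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, ]
    i <- which(qc$chrom == chr)
    if (!length(i)) next
    for (k in seq_len(nrow(iv))) {
      res[i] <- res[i] | (qc$start[i] < iv$end[k] & qc$end[i] > iv$start[k])
    }
  }
  res
}

#' Median-scale contact counts across probes
#'
#' Multiplies every count of a retained probe by its QC factor so that each
#' retained probe's total equals the median raw total of the retained set.
#' Removed probes are dropped from the output.
#'
#' @param contacts A `contact_table` or counts tibble.
#' @param qc Probe QC table from [probe_qc()].
#' @return Tibble of retained-probe contacts with an added `norm_count`
#'   column.
#' @export
normalize_contacts <- function(contacts, qc) {
  counts <- if (inherits(contacts, "contact_table")) contacts$counts else as_tibble(contacts)
  kept <- qc |> filter(status == "retained") |> select(bait, factor)
  if (!nrow(kept)) abort("no retained probes; cannot normalize")
  counts |>
    inner_join(kept, by = "bait") |>
    mutate(norm_count = count * factor) |>
    select(-factor)
}

#' Mask bait-proximal self-ligation signal
#'
#' Fragments any part of which lies within `exclusion_bp` of a bait's own
#' cut site carry high self- and near-ligation signal and are flagged masked
#' for that bait only (on the bait's chromosome). Masked entries are
#' flagged, not deleted, so files remain complete.
#'
#' @param contacts Contacts tibble (normalized or raw counts).
#' @param map A [restriction_map()].
#' @param baits Bait design table (provides each bait's cut site).
#' @param exclusion_bp Half-width of the exclusion window around the cut
#'   site; `0` masks only the fragment starting at the site.
#' @return The tibble with a logical `masked` column.
#' @export
mask_bait_proximal <- function(contacts, map, baits, exclusion_bp = 25000) {
  contacts <- as_tibble(contacts)
  bsite <- baits |> select(bait = name, bait_chrom = chrom, site_pos)
  out <- contacts |>
    left_join(bsite, by = "bait") |>
    mutate(masked = !is.na(site_pos) & chrom == bait_chrom &
             start <= site_pos + exclusion_bp & end > site_pos - exclusion_bp) |>
    select(-bait_chrom, -site_pos)
  out
}
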