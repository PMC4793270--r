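#' Replicate reproducibility of contact profiles
#'
#' Pearson correlation between two replicate contact profiles, restricted to
#' fragments with at least `min_count` reads in both replicates. Raising the
#' joint minimum count trims noise-dominated cells and typically increases
#' the correlation.
#'
#' @param data Data frame with one row per fragment (or per bait-fragment
#'   cell) and two replicate count columns.
#' @param min_count Joint minimum count filter.
#' @param rep1,rep2 Names of the two replicate count columns.
#' @return One-row tibble with `min_count`, `n_fragments` (surviving the
#'   filter) and `r`. Fewer than 3 surviving fragments, or a constant
#'   surviving vector, is an error.
#' @export
replicate_correlation <- function(data, min_count = 1,
                                  rep1 = "count1", rep2 = "count2") {
  data <- as_tibble(data)
  if (!all(c(rep1, rep2) %in% names(data))) {
    abort(paste0("`data` must have columns ", rep1, " and ", rep2))
  }
  x <- data[[rep1]]
  y <- data[[rep2]]
  keep <- x >= min_count & y >= min_count
  if (sum(keep) < 3) {
    abort("undefined correlation: fewer than 3 fragments pass the joint min-count filter")
  }
  x <- x[keep]
  y <- y[keep]
  if (var(x) == 0 || var(y) == 0) {
    abort("undefined correlation: filtered counts are constant")
  }
  tibble(min_count = min_count, n_fragments = sum(keep), r = cor(x, y))
}

#' 3C-qPCR contact frequency by the delta-delta-Ct method
#'
#' The ligation ratio of a primer pair is `E^-(mean Ct_3C - mean Ct_control)`,
#' where the control is a randomly ligated 3C control library. The contact
#' frequency of a test pair is its ratio divided by the ratio of the
#' adjacent-fragment reference pair, which normalizes loading, fixation and
#' ligation efficiency. Replicate scatter is propagated to a standard error
#' by the delta method on the mean Ct values.
#'
#' @param ct_3c_test,ct_control_test Ct replicate vectors for the test
#'   primer pair in the 3C library and the control library.
#' @param ct_3c_adjacent,ct_control_adjacent The same for the
#'   adjacent-fragment reference pair.
#' @param efficiency PCR amplification efficiency per cycle (2 = perfect
#'   doubling).
#' @return One-row tibble with `contact`, `se` and `ddct`.
#' @export
qpcr_contact <- function(ct_3c_test, ct_control_test,
                         ct_3c_adjacent, ct_control_adjacent,
                         efficiency = 2) {
  reps <- list(ct_3c_test, ct_control_test, ct_3c_adjacent, ct_control_adjacent)
  if (any(vapply(reps, length, 1L) < 1)) abort("each Ct list needs >= 1 replicate")
  if (!all(vapply(reps, function(v) all(is.finite(v) & v > 0), TRUE))) {
    abort("measurement error: Ct values must be finite and positive")
  }
  m <- vapply(reps, mean, 1)
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  contact <- efficiency^(-ddct)
  v_mean <- vapply(reps, function(v) if (length(v) > 1) var(v) / length(v) else NA_real_, 1)
  se <- contact * log(efficiency) * sqrt(sum(v_mean))
  tibble(contact = contact, se = se, ddct = ddct)
}

#' Process a qPCR Ct table against its adjacent-fragment reference
#'
#' @param data Long tibble with columns `pair_id`, `is_adjacent_reference`,
#'   `library_type` (`"c3"` or `"control"`) and `ct` (one row per
#'   replicate). Exactly one `pair_id` must be flagged as the adjacent
#'   reference.
#' @param efficiency PCR efficiency passed to [qpcr_contact()].
#' @return Tibble with one row per non-reference pair: `pair_id`,
#'   `contact`, `se`, `ddct`.
#' @export
qpcr_table <- function(data, efficiency = 2) {
  data <- as_tibble(data)
  req <- c("pair_id", "is_adjacent_reference", "library_type", "ct")
  if (!all(req %in% names(data))) {
    abort(paste0("`data` must have columns ", paste(req, collapse = ", ")))
  }
  adj_ids <- unique(data$pair_id[data$is_adjacent_reference])
  if (length(adj_ids) != 1) abort("exactly one adjacent reference pair required")
  pull_ct <- function(id, lib) data$ct[data$pair_id == id & data$library_type == lib]
  adj_c3 <- pull_ct(adj_ids, "c3")
  adj_ctrl <- pull_ct(adj_ids, "control")
  ids <- setdiff(unique(data$pair_id), adj_ids)
  purrr::map_dfr(ids, function(id) {
    qpcr_contact(pull_ct(id, "c3"), pull_ct(id, "control"),
                 adj_c3, adj_ctrl, efficiency) |>
      mutate(pair_id = id, .before = 1)
  })
}

#' eQTL simple linear regression of expression on genotype dosage
#'
#' Ordinary least squares of expression (RPKM) on additive genotype dosage
#' (0/1/2), with a two-sided t-test on the slope (n - 2 degrees of freedom).
#' A constant expression vector returns slope 0 with p = 1; a perfect fit
#' saturates at the smallest representable p-value.
#'
#' @param genotype Numeric dosage vector.
#' @param expression Numeric expression vector of the same length (n >= 3).
#' @return One-row tibble with `n`, `slope`, `se`, `statistic`, `p_value`.
#' @export
eqtl_regress <- function(genotype, expression) {
  n <- length(genotype)
  if (length(expression) != n) abort("genotype and expression lengths differ")
  if (n < 3) abort("need at least 3 samples")
  if (!all(is.finite(genotype)) || !all(is.finite(expression))) {
    abort("non-finite genotype or expression values")
  }
  if (var(genotype) == 0) abort("monomorphic SNP: genotype has zero variance")
  if (var(expression) == 0) {
    return(tibble(n = n, slope = 0, se = 0, statistic = NA_real_, p_value = 1))
  }
  fit <- lm(expression ~ genotype)
  # a perfect fit saturates p at the smallest double; silence summary.lm's
  # reliability warning for that deliberate case
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["genotype", "Estimate"]
  se <- cf["genotype", "Std. Error"]
  tstat <- slope / se
  p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  tibble(n = n, slope = slope, se = se, statistic = tstat, p_value = p)
}

#' eQTL scan over SNP-gene pairs
#'
#' Runs [eqtl_regress()] for each requested SNP-gene pair and reports raw
#' p-values alongside a Benjamini-Hochberg adjusted column (`p_bh`, labeled
#' extra, not a replacement).
#'
#' @param genotypes Long tibble (`sample_id`, `rsid`, `dosage`).
#' @param expression Long tibble (`sample_id`, `gene`, `rpkm`).
#' @param pairs Optional tibble (`rsid`, `gene`); default all combinations.
#' @return Tibble with one row per pair: `rsid`, `gene`, `n`, `slope`, `se`,
#'   `statistic`, `p_value`, `p_bh`.
#' @export
eqtl_scan <- function(genotypes, expression, pairs = NULL) {
  genotypes <- as_tibble(genotypes)
  expression <- as_tibble(expression)
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(rsid = unique(genotypes$rsid),
                                gene = unique(expression$gene))
  }
  out <- purrr::pmap_dfr(pairs, function(rsid, gene, ...) {
    g <- genotypes[genotypes$rsid == rsid, c("sample_id", "dosage")]
    y <- expression[expression$gene == gene, c("sample_id", "rpkm")]
    m <- inner_join(g, y, by = "sample_id")
    eqtl_regress(m$dosage, m$rpkm) |>
      mutate(rsid = rsid, gene = gene, .before = 1)
  })
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out
}

#' Annotate intervals with overlapping epigenomic tracks
#'
#' Any-overlap (>= 1 bp, half-open coordinates) of each feature against
#' named interval tracks (e.g. ChIP-seq peak sets). Feature order is
#' preserved; each (feature, track) overlap is reported once.
#'
#' @param features Tibble of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open; other columns carried through).
#' @param tracks Named list of interval tibbles, or one tibble with a
#'   `track` column.
#' @return `features` with an added `overlaps` list-column of overlapping
#'   track names (character(0) when none).
#' @export
annotate_overlap <- function(features, tracks) {
  features <- as_tibble(features)
  if (is.data.frame(tracks)) {
    if (!"track" %in% names(tracks)) abort("single-table `tracks` needs a `track` column")
    tracks <- split(as_tibble(tracks), tracks$track)
  }
  .check_intervals <- function(x, what) {
    if (any(x$start >= x$end)) {
      bad <- which(x$start >= x$end)[1]
      abort(paste0("malformed ", what, " interval at row ", bad, ": start >= end"))
    }
  }
  .check_intervals(features, "feature")
  f_gr <- GenomicRanges::GRanges(features$chrom,
                                 IRanges::IRanges(features$start + 1, features$end))
  hits_by_feature <- vector("list", nrow(features))
  for (nm in names(tracks)) {
    tr <- as_tibble(tracks[[nm]])
    .check_intervals(tr, paste0("track '", nm, "'"))
    t_gr <- GenomicRanges::GRanges(tr$chrom,
                                   IRanges::IRanges(tr$start + 1, tr$end))
    ov <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(f_gr, t_gr)))
    for (i in ov) hits_by_feature[[i]] <- c(hits_by_feature[[i]], nm)
  }
  features$overlaps <- lapply(hits_by_feature, function(v) v %||% character(0))
  features
}
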