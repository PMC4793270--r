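#' Configuration for permutation-based interaction calling
#'
#' Defaults follow the study design the package implements: window of one
#' fragment, 1000 permutations, candidate threshold at the top fifth
#' percentile of the permuted distribution, FDR 0.01.
#'
#' @param window Window width in fragments (sliding, step 1).
#' @param n_perm Number of permutations.
#' @param fdr Target false discovery rate, in (0, 1).
#' @param top_pct Percentile (of pooled permuted window counts) defining the
#'   candidate threshold.
#' @param seed Integer seed for the permutation stream, or `NULL` to use the
#'   current RNG state.
#' @return A `sig_config` list.
#' @export
sig_config <- function(window = 1L, n_perm = 1000L, fdr = 0.01,
                       top_pct = 5, seed = 1L) {
  if (window < 1) abort("`window` must be >= 1")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  if (fdr <= 0 || fdr >= 1) abort("`fdr` must be in (0, 1)")
  if (top_pct <= 0 || top_pct >= 100) abort("`top_pct` must be in (0, 100)")
  structure(list(window = as.integer(window), n_perm = as.integer(n_perm),
                 fdr = fdr, top_pct = top_pct, seed = seed),
            class = "sig_config")
}

# sliding window sums of width w, step 1
.window_sums <- function(x, w) {
  if (w == 1L) return(x)
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]
}

#' Permutation null for a per-bait contact profile
#'
#' Each permutation redistributes the observed reads uniformly among the
#' mappable fragments (a multinomial draw with equal cell probabilities) and
#' sums counts over sliding windows.
#'
#' @param n_reads Total reads in the profile (`N >= 1`).
#' @param n_fragments Number of mappable fragments (`M >= 2`).
#' @param config A [sig_config()]. Its `seed`, if non-NULL, seeds the draw.
#' @return Integer matrix of window counts, windows x permutations.
#' @export
permute_null <- function(n_reads, n_fragments, config = sig_config()) {
  if (n_fragments < 2) abort("need at least 2 mappable fragments")
  if (n_reads < 1) abort("empty profile: no reads to permute")
  if (!is.null(config$seed)) set.seed(config$seed)
  perm <- rmultinom(config$n_perm, n_reads, rep(1 / n_fragments, n_fragments))
  if (config$window > 1L) {
    perm <- apply(perm, 2, .window_sums, w = config$window)
    if (is.null(dim(perm))) perm <- matrix(perm, nrow = 1L)
  }
  perm
}

#' Call significant interactions for one contact profile
#'
#' Implements the permutation scheme used for capture-3C peak calling:
#' observed reads are shuffled uniformly among the mappable fragments, a
#' candidate count threshold is taken at the top `top_pct` percentile of the
#' pooled permuted window counts, and the final threshold is the smallest
#' count `c` at or above the candidate whose estimated FDR
#' (mean permuted windows `>= c` per permutation, divided by observed
#' windows `>= c`) is at most `fdr`. If no such count exists nothing is
#' called. Per-window empirical p-values are
#' `(1 + #permuted >= c) / (n_perm * W + 1)`.
#'
#' @param counts Integer vector of observed counts over the mappable
#'   (unmasked) fragments of one bait's chromosome.
#' @param config A [sig_config()].
#' @return A `sig_result`: list with `table` (tibble `window_idx`, `count`,
#'   `p`, `significant`), `threshold`, `fdr_at_threshold`, `candidate`
#'   (the top-percentile count), `n_reads`, `n_fragments`, `n_windows`,
#'   `config`. `tidy()` returns the table, `glance()` the scalars.
#' @export
call_significant <- function(counts, config = sig_config()) {
  counts <- as.integer(counts)
  M <- length(counts)
  if (M < 2) abort("degenerate profile: need at least 2 mappable fragments")
  N <- sum(counts)
  if (N < 1) abort("empty profile: no reads to permute")
  w <- config$window
  perm <- permute_null(N, M, config)
  obs <- .window_sums(counts, w)
  W <- length(obs)
  pooled <- as.integer(perm)
  maxv <- max(pooled, obs)
  # ge_pool[c + 1] = number of pooled permuted window counts >= c, c = 0..maxv+1
  ge_pool <- c(rev(cumsum(rev(tabulate(pooled + 1L, nbins = maxv + 1L)))), 0L)
  ge_obs <- c(rev(cumsum(rev(tabulate(obs + 1L, nbins = maxv + 1L)))), 0L)
  surv <- ge_pool / length(pooled)
  candidate <- which(surv <= config$top_pct / 100)[1] - 1L
  fdr_c <- (ge_pool / config$n_perm) / pmax(1L, ge_obs)
  ok <- which(fdr_c <= config$fdr & seq_along(fdr_c) - 1L >= candidate)
  threshold <- if (length(ok)) ok[1] - 1L else Inf
  p <- (1 + ge_pool[obs + 1L]) / (length(pooled) + 1)
  significant <- is.finite(threshold) & obs >= threshold
  structure(list(
    table = tibble(window_idx = seq_len(W), count = obs, p = p,
                   significant = significant),
    threshold = threshold,
    fdr_at_threshold = if (is.finite(threshold)) fdr_c[threshold + 1L] else NA_real_,
    candidate = candidate,
    n_reads = N, n_fragments = M, n_windows = W,
    config = config
  ), class = "sig_result")
}

#' @export
print.sig_result <- function(x, ...) {
  cat("<sig_result> N =", x$n_reads, "reads over M =", x$n_fragments,
      "fragments; threshold", x$threshold, "->",
      sum(x$table$significant), "significant window(s)\n")
  invisible(x)
}

#' @rdname call_significant
#' @param x A `sig_result`.
#' @param ... Unused.
#' @export
tidy.sig_result <- function(x, ...) x$table

#' @rdname call_significant
#' @export
glance.sig_result <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_fragments = x$n_fragments,
         n_windows = x$n_windows, candidate = x$candidate,
         threshold = x$threshold, fdr_at_threshold = x$fdr_at_threshold,
         n_significant = sum(x$table$significant))
}

#' Call significant cis-interactions for every bait
#'
#' For each bait (in bait-table order), the mappable profile is the complete
#' set of fragments on the bait's chromosome, excluding fragments within
#' `exclusion_bp` of the bait's own cut site; fragments without observed
#' reads count zero. Significance is computed on raw integer counts — the
#' permutation null conserves the integer read total, and probe
#' normalization only rescales whole profiles, which cannot change a
#' within-profile permutation call. Trans fragments are not tested. One
#' seeded generator drives all baits (per-bait, per-permutation consumption
#' order).
#'
#' @param contacts A `contact_table` or raw-count contacts tibble.
#' @param map A [restriction_map()].
#' @param baits Bait table (possibly filtered to retained probes).
#' @param config A [sig_config()].
#' @param exclusion_bp Bait-proximal exclusion half-width in bp.
#' @return A `sig_calls` object: list with `table` (per-fragment tibble with
#'   `bait`, `chrom`, `frag_idx`, `start`, `end`, `count`, `p`,
#'   `significant`) and `baits` (per-bait threshold summary). `tidy()` /
#'   `glance()` return them. With `window > 1` rows are windows; `frag_idx`,
#'   `start` and `end` span the window.
#' @export
call_interactions <- function(contacts, map, baits, config = sig_config(),
                              exclusion_bp = 25000) {
  counts <- if (inherits(contacts, "contact_table")) contacts$counts else as_tibble(contacts)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  w <- config$window
  tables <- list()
  summaries <- list()
  for (k in seq_len(nrow(baits))) {
    b <- baits$name[k]
    chr <- baits$chrom[k]
    site <- baits$site_pos[k]
    frs <- fragments(map, chr)
    keep <- !(frs$start <= site + exclusion_bp & frs$end > site - exclusion_bp)
    frs <- frs[keep, ]
    if (nrow(frs) < 2) next
    bc <- counts[counts$bait == b & counts$chrom == chr, c("frag_idx", "count")]
    vec <- integer(nrow(frs))
    hit <- match(bc$frag_idx, frs$frag_idx)
    vec[hit[!is.na(hit)]] <- bc$count[!is.na(hit)]
    if (sum(vec) < 1) next
    res <- call_significant(vec, cfg)
    tab <- res$table
    i0 <- tab$window_idx
    tables[[b]] <- tibble(
      bait = b, chrom = chr,
      frag_idx = frs$frag_idx[i0],
      start = frs$start[i0],
      end = frs$end[pmin(i0 + w - 1L, nrow(frs))],
      count = tab$count, p = tab$p, significant = tab$significant
    )
    summaries[[b]] <- glance(res) |> mutate(bait = b, .before = 1)
  }
  structure(list(table = bind_rows(tables), baits = bind_rows(summaries),
                 config = config, exclusion_bp = exclusion_bp),
            class = "sig_calls")
}

#' @export
print.sig_calls <- function(x, ...) {
  cat("<sig_calls> ", nrow(x$baits), " bait(s) tested, ",
      sum(x$table$significant), " significant window(s)\n", sep = "")
  invisible(x)
}

#' @rdname call_interactions
#' @param x A `sig_calls` object.
#' @param ... Unused.
#' @export
tidy.sig_calls <- function(x, ...) x$table

#' @rdname call_interactions
#' @export
glance.sig_calls <- function(x, ...) x$baits
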