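# Independent brute-force oracles and tiny fixtures shared across tests.

# naive O(n*m) sliding-window motif scan
oracle_digest <- function(sequence, motif) {
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  n <- length(s) - length(m) + 1
  if (n < 1) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (all(s[i:(i + length(m) - 1)] == m)) hits <- c(hits, i - 1L)
  }
  hits
}

# brute-force fragment assignment + nearest-site distance for one coordinate
oracle_assign <- function(sites, chrom_len, pos) {
  bounds <- unique(c(0, sites, chrom_len))
  frag <- max(which(bounds[-length(bounds)] <= pos))
  dist <- if (length(sites)) min(abs(pos - sites)) else Inf
  list(frag_idx = frag, dist = dist)
}

# all-pairs interval overlap, half-open
oracle_overlap <- function(features, track) {
  hits <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(track))) {
      if (features$chrom[i] == track$chrom[j] &&
          features$start[i] < track$end[j] &&
          features$end[i] > track$start[j]) {
        hits[i] <- TRUE
        break
      }
    }
  }
  hits
}

# closed-form OLS via the normal equations, independent of lm()
oracle_ols <- function(g, y) {
  n <- length(g)
  sxx <- sum((g - mean(g))^2)
  b <- sum((g - mean(g)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(g)
  rss <- sum((y - a - b * g)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- b / se
  list(slope = b, se = se, t = t, p = 2 * pt(-abs(t), n - 2))
}

# naive re-implementation of the permutation threshold / FDR logic, fed the
# same permutation matrix; loops instead of tabulated survivals
oracle_call <- function(counts, perm, fdr = 0.01, top_pct = 5) {
  pooled <- as.vector(perm)
  n_perm <- ncol(perm)
  maxv <- max(pooled, counts)
  t0 <- NA
  for (c0 in 0:(maxv + 1)) {
    if (mean(pooled >= c0) <= top_pct / 100) { t0 <- c0; break }
  }
  threshold <- Inf
  for (c0 in t0:(maxv + 1)) {
    e_perm <- sum(pooled >= c0) / n_perm
    n_obs <- sum(counts >= c0)
    if (e_perm / max(1, n_obs) <= fdr) { threshold <- c0; break }
  }
  list(candidate = t0, threshold = threshold,
       significant = is.finite(threshold) & counts >= threshold)
}

# small deterministic toy map: 2 chromosomes
toy_map <- function() {
  restriction_map(
    tibble::tibble(
      chrom = c(rep("chrA", 4), rep("chrB", 2)),
      pos = c(1000, 5000, 9000, 15000, 3000, 12000)
    ),
    c(chrA = 20000, chrB = 18000)
  )
}

toy_loci <- function() {
  tibble::tibble(name = "locA", chrom = "chrA", start = 500, end = 16000,
                 prefix = "")
}

toy_baits <- function(flank = 250) {
  design_baits(toy_map(), toy_loci(), flank = flank)
}

# one small simulated experiment reused by several tests
small_sim <- function(seed = 11, n_pairs = 15000, ...) {
  cfg <- sim_config(seed = seed, n_pairs = n_pairs, ...)
  genome <- simulate_genome(cfg)
  sim <- simulate_pairs(genome, cfg)
  list(cfg = cfg, genome = genome, pairs = sim$pairs, truth = sim$truth)
}
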