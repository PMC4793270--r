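#' Configuration for the synthetic proximity-ligation generator
#'
#' The generator emulates a multi-locus capture-3C library: cut sites with
#' exponential spacing, target loci of at least ten cut sites each, a
#' power-law ligation-frequency decay with genomic distance, per-probe
#' capture-efficiency variation, a configurable trans and off-target
#' fraction, PCR duplicates, and planted bait-fragment interactions with a
#' known fold enrichment.
#'
#' @param seed Integer seed; the whole simulation is reproducible from
#'   (config, seed).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param cut_spacing Mean inter-site spacing in bp (exponential gaps).
#' @param loci Tibble (`chrom`, `n_sites`): one target locus per row,
#'   containing that many consecutive cut sites.
#' @param n_pairs Total read pairs before duplication.
#' @param alpha Distance-decay exponent (contact frequency ~ `(d + d0)^-alpha`).
#' @param d0 Decay stabilizer in bp.
#' @param trans_rate Fraction of on-target pairs whose partner end is on
#'   another chromosome.
#' @param off_target_rate Fraction of pairs with neither end bait-proximal.
#' @param dup_rate Probability that an emitted pair is duplicated.
#' @param clonal_rate Probability that an on-target pair seeds a
#'   library-specific clonal amplification cluster: extra copies with
#'   coordinates jittered by a few bp, which exact-coordinate
#'   deduplication cannot remove (the PCR-jackpot artifacts that motivate
#'   min-count filtering in replicate comparisons). Default 0: off.
#' @param clonal_size_mean Mean number of extra copies per clonal cluster
#'   (geometric).
#' @param probe_sigma Log-SD of per-probe capture-efficiency factors.
#' @param flank Probe flank width in bp.
#' @param planted Optional tibble (`bait`, `chrom`, `frag_idx`, `fold`):
#'   bait-fragment pairs receiving a multiplicative enrichment (fold >= 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       cut_spacing = 4096,
                       loci = tibble(chrom = c("chr1", "chr1", "chr2"),
                                     n_sites = c(17L, 12L, 10L)),
                       n_pairs = 1e5,
                       alpha = 1, d0 = 1000,
                       trans_rate = 0.10,
                       off_target_rate = 0.5,
                       dup_rate = 0.05,
                       clonal_rate = 0,
                       clonal_size_mean = 5,
                       probe_sigma = 0.5,
                       flank = 250,
                       planted = NULL) {
  rates <- c(trans_rate, off_target_rate, dup_rate, clonal_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (clonal_size_mean <= 0) abort("`clonal_size_mean` must be positive")
  if (alpha <= 0) abort("`alpha` must be positive")
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (!all(c("bait", "chrom", "frag_idx", "fold") %in% names(planted))) {
      abort("`planted` needs columns bait, chrom, frag_idx, fold")
    }
    if (any(planted$fold < 1)) abort("planted fold must be >= 1")
  }
  if (trans_rate > 0 && length(chrom_lengths) < 2) {
    abort("trans pairs require at least 2 chromosomes")
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 cut_spacing = cut_spacing, loci = as_tibble(loci),
                 n_pairs = n_pairs, alpha = alpha, d0 = d0,
                 trans_rate = trans_rate, off_target_rate = off_target_rate,
                 dup_rate = dup_rate, clonal_rate = clonal_rate,
                 clonal_size_mean = clonal_size_mean, probe_sigma = probe_sigma,
                 flank = flank, planted = planted),
            class = "sim_config")
}

#' Simulate a capture design: restriction map, loci and baits
#'
#' Cut sites are placed with exponential inter-site spacing. Each requested
#' locus is a run of consecutive cut sites (at least 10, mirroring the
#' smallest realistic capture locus) placed without overlap along its
#' chromosome; locus prefixes follow coordinate order (`A`, `B`, ... when a
#' chromosome carries several loci, empty otherwise).
#'
#' @param config A [sim_config()].
#' @return List of class `c3c_genome` with elements `map`
#'   ([restriction_map()]), `loci` and `baits`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- config$chrom_lengths
  sites <- purrr::imap_dfr(as.list(lens), function(L, chr) {
    gaps <- rexp(ceiling(2.5 * L / config$cut_spacing), 1 / config$cut_spacing)
    s <- floor(cumsum(gaps))
    s <- unique(s[s > 0 & s <= L - 6])
    tibble(chrom = chr, pos = s)
  })
  map <- restriction_map(sites, lens)

  loci_req <- config$loci
  loci_rows <- list()
  for (chr in unique(loci_req$chrom)) {
    want <- loci_req$n_sites[loci_req$chrom == chr]
    if (any(want < 10)) abort("each locus must contain at least 10 cut sites")
    s <- .map_sites(map, chr)
    buffer <- 5L
    need <- sum(want) + buffer * (length(want) - 1L)
    if (need > length(s)) {
      abort(paste0("chromosome ", chr, " too short: ", length(s),
                   " cut sites available, ", need, " required for its loci"))
    }
    slack <- length(s) - need
    offsets <- sort(sample.int(slack + 1L, length(want), replace = TRUE) - 1L)
    start_idx <- integer(length(want))
    cursor <- 1L
    for (i in seq_along(want)) {
      start_idx[i] <- cursor + offsets[i]
      cursor <- cursor + want[i] + buffer
    }
    pad <- 2 * config$flank
    for (i in seq_along(want)) {
      i1 <- start_idx[i]
      i2 <- start_idx[i] + want[i] - 1L
      # clamp the padding so no site outside the run is swallowed
      lo <- if (i1 > 1L) s[i1 - 1L] + 1 else 0
      hi <- if (i2 < length(s)) s[i2 + 1L] else lens[[chr]]
      loci_rows[[length(loci_rows) + 1L]] <- tibble(
        chrom = chr,
        start = max(s[i1] - pad, lo, 0),
        end = min(s[i2] + pad, hi, lens[[chr]]),
        n_sites = want[i]
      )
    }
  }
  loci <- bind_rows(loci_rows) |>
    group_by(chrom) |>
    arrange(start, .by_group = TRUE) |>
    mutate(prefix = if (n() > 1) LETTERS[row_number()] else "") |>
    ungroup() |>
    mutate(name = paste0(chrom, ifelse(prefix == "", "", paste0("_", prefix)))) |>
    select(name, chrom, start, end, prefix, n_sites)

  baits <- design_baits(map, loci, flank = config$flank)
  structure(list(map = map, loci = loci, baits = baits), class = "c3c_genome")
}

#' @export
print.c3c_genome <- function(x, ...) {
  cat("<c3c_genome> ", nrow(x$map$sites), " cut sites, ", nrow(x$loci),
      " loci, ", nrow(x$baits), " baits\n", sep = "")
  invisible(x)
}

# uniform genomic positions avoiding bait-proximal windows, so that the
# generated category is exactly what the pipeline will classify
.runif_offtarget <- function(genome, config, n) {
  lens <- config$chrom_lengths
  chroms <- names(lens)
  out_chrom <- character(n)
  out_pos <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    ch <- sample(chroms, length(todo), replace = TRUE, prob = lens)
    po <- floor(runif(length(todo)) * lens[ch])
    anch <- .anchor_ends(genome$map, genome$baits, genome$loci, ch, po,
                         config$flank)
    ok <- is.na(anch$bait)
    out_chrom[todo[ok]] <- ch[ok]
    out_pos[todo[ok]] <- po[ok]
    todo <- todo[!ok]
  }
  list(chrom = out_chrom, pos = out_pos)
}

#' Simulate a capture-3C paired-end alignment table with known truth
#'
#' On-target pairs anchor inside a bait region chosen proportionally to its
#' capture-efficiency factor (log-normal, SD `probe_sigma`). The cis partner
#' fragment is drawn with weight `len * (distance + d0)^-alpha`, multiplied
#' by the planted fold for planted (bait, fragment) pairs; the partner
#' coordinate is uniform within the flank of one of the fragment's cut-site
#' boundaries. Trans partners are uniform on other chromosomes; off-target
#' pairs are uniform genome-wide outside bait-proximal windows. Each emitted
#' pair is finally duplicated (exact coordinate copy) with probability
#' `dup_rate` and the table is shuffled.
#'
#' @param genome A `c3c_genome` from [simulate_genome()].
#' @param config A [sim_config()].
#' @param efficiency Optional tibble (`bait`, `factor`) fixing the per-probe
#'   efficiency factors (to share truth across replicate libraries);
#'   default drawn log-normally.
#' @param seed Seed for the read-sampling stream; default `config$seed + 1`
#'   so genome and reads are independently reproducible.
#' @return List with `pairs` (tibble `chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`) and `truth` (class `c3c_truth`): config echo,
#'   efficiency factors, planted table, per-category counts, and the exact
#'   number of duplicate rows in the emitted table.
#' @export
simulate_pairs <- function(genome, config, efficiency = NULL, seed = NULL) {
  stopifnot(inherits(genome, "c3c_genome"), inherits(config, "sim_config"))
  set.seed(seed %||% (config$seed + 1L))
  map <- genome$map
  baits <- genome$baits
  lens <- config$chrom_lengths
  P <- nrow(baits)
  if (is.null(efficiency)) {
    efficiency <- tibble(bait = baits$name,
                         factor = exp(rnorm(P, 0, config$probe_sigma)))
  }
  eff <- efficiency$factor[match(baits$name, efficiency$bait)]

  n <- config$n_pairs
  category <- sample(c("off_target", "on_target_trans", "on_target_cis"), n,
                     replace = TRUE,
                     prob = c(config$off_target_rate,
                              (1 - config$off_target_rate) * config$trans_rate,
                              (1 - config$off_target_rate) * (1 - config$trans_rate)))
  chrom1 <- character(n); pos1 <- numeric(n)
  chrom2 <- character(n); pos2 <- numeric(n)

  i_off <- which(category == "off_target")
  if (length(i_off)) {
    e1 <- .runif_offtarget(genome, config, length(i_off))
    e2 <- .runif_offtarget(genome, config, length(i_off))
    chrom1[i_off] <- e1$chrom; pos1[i_off] <- e1$pos
    chrom2[i_off] <- e2$chrom; pos2[i_off] <- e2$pos
  }

  i_on <- which(category != "off_target")
  if (length(i_on)) {
    bk <- sample.int(P, length(i_on), replace = TRUE, prob = eff)
    bstart <- baits$start[bk]; bend <- baits$end[bk]
    chrom1[i_on] <- baits$chrom[bk]
    pos1[i_on] <- floor(bstart + runif(length(i_on)) * (bend - bstart))
  }

  i_tr <- which(category == "on_target_trans")
  if (length(i_tr)) {
    bchr <- chrom1[i_tr]
    other <- lapply(names(lens), function(c0) setdiff(names(lens), c0))
    names(other) <- names(lens)
    ch <- vapply(bchr, function(c0) {
      oc <- other[[c0]]
      sample(oc, 1L, prob = lens[oc])
    }, "")
    chrom2[i_tr] <- ch
    pos2[i_tr] <- floor(runif(length(i_tr)) * lens[ch])
  }

  i_cis <- which(category == "on_target_cis")
  if (length(i_cis)) {
    frs_all <- fragments(map)
    bk_on <- integer(n)
    bk_on[i_on] <- bk
    for (b in unique(bk_on[i_cis])) {
      rows <- i_cis[bk_on[i_cis] == b]
      chr <- baits$chrom[b]
      site <- baits$site_pos[b]
      fr <- frs_all[frs_all$chrom == chr, ]
      mid <- (fr$start + fr$end) / 2
      wt <- (fr$end - fr$start) * (abs(mid - site) + config$d0)^(-config$alpha)
      if (!is.null(config$planted)) {
        pl <- config$planted[config$planted$bait == baits$name[b] &
                               config$planted$chrom == chr, ]
        if (nrow(pl)) {
          j <- match(pl$frag_idx, fr$frag_idx)
          wt[j[!is.na(j)]] <- wt[j[!is.na(j)]] * pl$fold[!is.na(j)]
        }
      }
      fi <- sample.int(nrow(fr), length(rows), replace = TRUE, prob = wt)
      fstart <- fr$start[fi]; fend <- fr$end[fi]
      # position near a cut-site boundary of the chosen fragment: the start
      # boundary is a cut site unless it is the chromosome start, the end
      # boundary unless it is the chromosome end
      has_left <- fstart > 0
      has_right <- fend < lens[[chr]]
      use_left <- ifelse(has_left & has_right, runif(length(rows)) < 0.5, has_left)
      span <- pmin(config$flank, fend - fstart)
      off <- floor(runif(length(rows)) * span)
      pos2[rows] <- ifelse(use_left, fstart + off, fend - 1 - off)
      chrom2[rows] <- chr
    }
  }

  # library-specific clonal amplification clusters: jittered near-copies of
  # on-target pairs that exact-coordinate deduplication cannot collapse
  if (config$clonal_rate > 0 && length(i_on)) {
    bk_on2 <- integer(n)
    bk_on2[i_on] <- bk
    seeds <- i_on[runif(length(i_on)) < config$clonal_rate]
    if (length(seeds)) {
      sizes <- stats::rgeom(length(seeds),
                            1 / (1 + config$clonal_size_mean))
      rep_idx <- rep(seeds, sizes)
      if (length(rep_idx)) {
        bs <- bk_on2[rep_idx]
        j1 <- sample(-5:5, length(rep_idx), replace = TRUE)
        j2 <- sample(-5:5, length(rep_idx), replace = TRUE)
        # the jittered anchor stays inside its bait interval so the copy's
        # category is exactly the seed's
        p1 <- pmin(pmax(pos1[rep_idx] + j1, baits$start[bs]),
                   baits$end[bs] - 1)
        p2 <- pmin(pmax(pos2[rep_idx] + j2, 0),
                   lens[chrom2[rep_idx]] - 1)
        chrom1 <- c(chrom1, chrom1[rep_idx])
        pos1 <- c(pos1, p1)
        chrom2 <- c(chrom2, chrom2[rep_idx])
        pos2 <- c(pos2, unname(p2))
        category <- c(category, category[rep_idx])
      }
    }
  }
  n_out <- length(pos1)
  strand_pool <- c("+", "-")
  pairs <- tibble(
    chrom1 = chrom1, pos1 = pos1,
    strand1 = sample(strand_pool, n_out, replace = TRUE),
    chrom2 = chrom2, pos2 = pos2,
    strand2 = sample(strand_pool, n_out, replace = TRUE)
  )
  # random end order on output; the pipeline canonicalizes
  flip <- runif(n_out) < 0.5
  pairs[flip, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
    pairs[flip, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]

  dup <- runif(n_out) < config$dup_rate
  emitted <- bind_rows(pairs, pairs[dup, ])
  emitted <- emitted[sample.int(nrow(emitted)), ]

  canon <- canonical_pairs(emitted)
  key <- paste(canon$chrom1, canon$pos1, canon$strand1,
               canon$chrom2, canon$pos2, canon$strand2, sep = "\r")
  cat_levels <- c("on_target_cis", "on_target_trans", "off_target")
  cat_counts <- vapply(cat_levels, function(cc) sum(category == cc), 1L,
                       USE.NAMES = FALSE)
  truth <- structure(list(
    config = config,
    efficiency = efficiency,
    planted = config$planted,
    categories = tibble(category = cat_levels, n = cat_counts),
    n_unique_pairs = n_out,
    n_emitted = nrow(emitted),
    n_duplicates = sum(duplicated(key))
  ), class = "c3c_truth")
  list(pairs = emitted, truth = truth)
}

#' @export
print.c3c_truth <- function(x, ...) {
  cat("<c3c_truth> ", x$n_unique_pairs, " unique pairs, ", x$n_duplicates,
      " duplicate rows emitted\n", sep = "")
  print(x$categories)
  invisible(x)
}
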