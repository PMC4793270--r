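test_that("replicate correlation applies the joint min-count filter", {
  d <- tibble::tibble(count1 = c(1, 3, 4, 5), count2 = c(1, 3, 4, 5))
  expect_equal(replicate_correlation(d, 1)$r, 1)
  d2 <- tibble::tibble(count1 = 1:3, count2 = 3:1)
  expect_equal(replicate_correlation(d2, 1)$r, -1)
  # filter leaves 2 points -> undefined
  d3 <- tibble::tibble(count1 = c(0, 2, 5, 7), count2 = c(1, 0, 4, 8))
  expect_error(replicate_correlation(d3, 1), "fewer than 3")
  # constant after filtering -> undefined
  d4 <- tibble::tibble(count1 = c(2, 2, 2), count2 = c(1, 5, 9))
  expect_error(replicate_correlation(d4, 1), "constant")
  expect_equal(replicate_correlation(d, 3)$n_fragments, 3)
})

test_that("replicate correlation is high on resampled libraries sharing truth", {
  # one genome and efficiency set, two independently sampled libraries
  cfg <- sim_config(seed = 500, chrom_lengths = c(chr1 = 5e5),
                    loci = tibble::tibble(chrom = "chr1", n_sites = 10),
                    n_pairs = 8000, trans_rate = 0, off_target_rate = 0.2,
                    dup_rate = 0)
  genome <- simulate_genome(cfg)
  set.seed(501)
  eff <- tibble::tibble(bait = genome$baits$name,
                        factor = exp(rnorm(nrow(genome$baits), 0, 0.5)))
  s1 <- simulate_pairs(genome, cfg, efficiency = eff, seed = 1000)
  s2 <- simulate_pairs(genome, cfg, efficiency = eff, seed = 1001)
  c1 <- extract_contacts(s1$pairs, genome$map, genome$baits, genome$loci)
  c2 <- extract_contacts(s2$pairs, genome$map, genome$baits, genome$loci)
  j <- dplyr::full_join(
    dplyr::select(c1$counts, bait, chrom, frag_idx, count1 = count),
    dplyr::select(c2$counts, bait, chrom, frag_idx, count2 = count),
    by = c("bait", "chrom", "frag_idx")) |>
    tidyr::replace_na(list(count1 = 0, count2 = 0))
  r1 <- replicate_correlation(j, 1)
  r3 <- replicate_correlation(j, 3)
  expect_gt(r1$r, 0.8)
  expect_gt(r3$r, 0.8)
  # the stricter joint filter retains strictly fewer cells
  expect_lt(r3$n_fragments, r1$n_fragments)
  # filtering is monotone in min_count
  expect_equal(r3$n_fragments, sum(j$count1 >= 3 & j$count2 >= 3))
})

test_that("qpcr contact frequency reproduces 2^-ddCt arithmetic", {
  # all four means equal -> 1
  expect_equal(qpcr_contact(30, 30, 30, 30)$contact, 1)
  # worked example: 2^-((30-28)-(26-26)) = 0.25
  expect_equal(qpcr_contact(30, 28, 26, 26)$contact, 0.25)
  # swapping test and adjacent inverts the result exactly
  a <- qpcr_contact(c(31, 31.4), c(28, 28.2), c(26.1, 26.3), c(25.9, 26))
  b <- qpcr_contact(c(26.1, 26.3), c(25.9, 26), c(31, 31.4), c(28, 28.2))
  expect_equal(a$contact, 1 / b$contact)
  # invariant under adding a constant to all four mean Cts
  shift <- qpcr_contact(c(33, 33.4), c(30, 30.2), c(28.1, 28.3), c(27.9, 28))
  expect_equal(a$contact, shift$contact)
  expect_equal(a$se, shift$se)
  expect_error(qpcr_contact(NaN, 28, 26, 26), "measurement error")
})

test_that("qpcr_table normalizes every test pair to the adjacent reference", {
  d <- tibble::tibble(
    pair_id = rep(c("T6", "T7", "adj"), each = 6),
    is_adjacent_reference = rep(c(FALSE, FALSE, TRUE), each = 6),
    library_type = rep(rep(c("c3", "control"), each = 3), 3),
    ct = c(30, 30, 30, 28, 28, 28,
           32, 32, 32, 28, 28, 28,
           26, 26, 26, 26, 26, 26)
  )
  res <- qpcr_table(d)
  expect_equal(res$contact[res$pair_id == "T6"], 0.25)
  expect_equal(res$contact[res$pair_id == "T7"], 1 / 16)
})

test_that("eqtl regression matches the normal-equation oracle", {
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(1.0, 1.2, 2.1, 1.9, 3.0, 2.8)
  fit <- eqtl_regress(g, y)
  o <- oracle_ols(g, y)
  expect_equal(fit$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$se, o$se, tolerance = 1e-10)
  expect_equal(fit$p_value, o$p, tolerance = 1e-10)
  # constant expression -> slope 0, p 1
  flat <- eqtl_regress(g, rep(2, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
  # perfect fit saturates at the smallest representable p
  perf <- eqtl_regress(g, g)
  expect_equal(perf$slope, 1)
  expect_equal(perf$p_value, .Machine$double.xmin)
  expect_error(eqtl_regress(rep(1, 5), rnorm(5)), "monomorphic")
  expect_error(eqtl_regress(c(0, 1), c(1, 2)), "at least 3")
})

test_that("null eqtl p-values are uniform", {
  set.seed(314)
  p <- replicate(200, {
    g <- sample(0:2, 100, replace = TRUE)
    eqtl_regress(g, rnorm(100))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("eqtl scan joins samples and adds a BH column", {
  set.seed(8)
  samples <- paste0("s", 1:30)
  geno <- tidyr::expand_grid(sample_id = samples, rsid = c("rs1", "rs2")) |>
    dplyr::mutate(dosage = sample(0:2, dplyr::n(), replace = TRUE))
  g1 <- geno$dosage[geno$rsid == "rs1"]
  expr <- tibble::tibble(sample_id = samples, gene = "GENE1",
                         rpkm = 2 + 0.8 * g1 + rnorm(30, 0, 0.3))
  res <- eqtl_scan(geno, expr)
  expect_equal(nrow(res), 2)
  expect_true(res$p_value[res$rsid == "rs1"] < res$p_value[res$rsid == "rs2"])
  expect_true(all(res$p_bh >= res$p_value))
})

test_that("interval annotation matches a brute-force all-pairs oracle", {
  f <- tibble::tibble(chrom = "c", start = 100, end = 200)
  expect_equal(annotate_overlap(f, list(k = tibble::tibble(chrom = "c", start = 150, end = 300)))$overlaps[[1]], "k")
  # half-open: touching intervals do not overlap
  expect_equal(
    annotate_overlap(f, list(k = tibble::tibble(chrom = "c", start = 200, end = 300)))$overlaps[[1]],
    character(0))
  expect_error(
    annotate_overlap(tibble::tibble(chrom = "c", start = 5, end = 5), list()),
    "malformed")
  set.seed(64)
  feats <- tibble::tibble(chrom = sample(c("c1", "c2"), 400, replace = TRUE),
                          start = sample.int(1e5, 400))
  feats$end <- feats$start + sample.int(500, 400)
  trk <- tibble::tibble(chrom = sample(c("c1", "c2"), 400, replace = TRUE),
                        start = sample.int(1e5, 400))
  trk$end <- trk$start + sample.int(500, 400)
  ann <- annotate_overlap(feats, list(peaks = trk))
  expect_equal(lengths(ann$overlaps) > 0, oracle_overlap(feats, trk))
  # feature order preserved
  expect_equal(ann$start, feats$start)
})

test_that("pwm scoring and allele deltas behave as log2 odds", {
  uni <- pwm(matrix(0.25, 4, 5))
  expect_equal(pwm_score(uni, "ACGTA"), 0)
  expect_equal(pwm_allele_delta(uni, "AACGTAA", 4, "G", "C")$delta, 0)
  w1 <- pwm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1))
  d <- pwm_allele_delta(w1, "TTATT", 3, "A", "C")
  expect_equal(d$delta, log2(0.97 / 0.01), tolerance = 1e-9)
  # antisymmetry
  m <- matrix(c(8, 1, 1, 2, 1, 9, 1, 1, 2, 2, 6, 2), 4, 3)
  x <- pwm(m)
  ctx <- "GGACATGG"
  d12 <- pwm_allele_delta(x, ctx, 5, "A", "T")
  d21 <- pwm_allele_delta(x, ctx, 5, "T", "A")
  expect_equal(d12$delta, -d21$delta)
  # same allele -> zero
  expect_equal(pwm_allele_delta(x, ctx, 5, "A", "A")$delta, 0)
  expect_error(pwm_allele_delta(x, ctx, 5, "A", "N"), "invalid allele")
  # strand symmetry: scoring the reverse complement context gives equal best
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", ctx), "")[[1]]), collapse = "")
  d_rc <- pwm_allele_delta(x, rc, nchar(ctx) - 5 + 1, "T", "A")
  expect_equal(d_rc$delta, d12$delta)
})

test_that("jaspar matrices read into consistent probability columns", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TEST",
               "A  [ 4 19  0 ]",
               "C  [16  0 20 ]",
               "G  [ 0  1  0 ]",
               "T  [ 0  0  0 ]"), path)
  x <- read_jaspar(path)
  expect_s3_class(x, "pwm")
  expect_equal(x$width, 3)
  expect_true(all(abs(colSums(x$prob) - 1) < 1e-9))
  # inconsistent column totals rejected
  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c("A 10 1", "C 0 1", "G 0 1", "T 0 1"), bad)
  expect_error(read_jaspar(bad), "inconsistent")
})
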