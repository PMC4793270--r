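test_that("assign_end matches a brute-force nearest-site scan", {
  map <- toy_map()
  a <- assign_end(map, "chrA", 1200)
  expect_equal(a$frag_idx, 2L)
  expect_equal(a$dist, 200)
  expect_equal(assign_end(map, "chrA", 1000)$dist, 0)
  m2 <- restriction_map(tibble::tibble(chrom = "c", pos = c(1000, 5000)),
                        c(c = 10000))
  expect_equal(assign_end(m2, "c", 3000)$dist, 2000)
  expect_error(assign_end(map, "chrA", 25000), "out of range")

  set.seed(99)
  pos <- sample.int(20000, 2000) - 1L
  got <- assign_end(map, rep("chrA", length(pos)), pos)
  sites <- c(1000, 5000, 9000, 15000)
  for (i in seq_along(pos)) {
    exp <- oracle_assign(sites, 20000, pos[i])
    expect_identical(got$frag_idx[i], as.integer(exp$frag_idx))
    expect_identical(got$dist[i], as.numeric(exp$dist))
  }
})

test_that("pair classification follows the informative-pair definition", {
  map <- toy_map()
  baits <- toy_baits()
  loci <- toy_loci()
  mk <- function(c1, p1, c2, p2) {
    tibble::tibble(chrom1 = c1, pos1 = p1, strand1 = "+",
                   chrom2 = c2, pos2 = p2, strand2 = "+")
  }
  # end 200 bp from an in-locus cut site, partner far on same chromosome
  cls <- classify_pairs(mk("chrA", 5200, "chrA", 18000), map, baits, loci)
  expect_equal(cls$category, "on_target_cis")
  expect_equal(cls$bait1, "E2D")
  # 300 bp away: beyond the flank -> off-target
  cls <- classify_pairs(mk("chrA", 5300, "chrA", 18000), map, baits, loci)
  expect_equal(cls$category, "off_target")
  # exactly on the cut site, partner on another chromosome -> trans
  cls <- classify_pairs(mk("chrA", 9000, "chrB", 100), map, baits, loci)
  expect_equal(cls$category, "on_target_trans")
  expect_equal(cls$bait1, "E3D")
  # upstream flank boundary is included (half-open U interval)
  cls <- classify_pairs(mk("chrA", 4750, "chrA", 18000), map, baits, loci)
  expect_equal(cls$bait1, "E2U")
  # proximity to a cut site outside any locus is not informative
  off_loci <- tibble::tibble(name = "l", chrom = "chrA", start = 500,
                             end = 2000, prefix = "")
  off_baits <- design_baits(map, off_loci)
  cls <- classify_pairs(mk("chrA", 5100, "chrA", 18000), map, off_baits, off_loci)
  expect_equal(cls$category, "off_target")
})

test_that("deduplication keeps the first canonical occurrence", {
  p <- tibble::tibble(
    chrom1 = "chrA", pos1 = c(100, 100, 100), strand1 = "+",
    chrom2 = "chrA", pos2 = c(900, 900, 900), strand2 = "-"
  )
  d <- dedup_pairs(p)
  expect_equal(sum(d$duplicate), 2)
  # end-swapped twin compares equal after canonical ordering
  swapped <- tibble::tibble(
    chrom1 = c("chrA", "chrA"), pos1 = c(100, 900), strand1 = c("+", "-"),
    chrom2 = c("chrA", "chrA"), pos2 = c(900, 100), strand2 = c("-", "+")
  )
  expect_equal(sum(dedup_pairs(swapped)$duplicate), 1)
  # idempotent
  d2 <- dedup_pairs(d[!d$duplicate, names(p)])
  expect_equal(sum(d2$duplicate), 0)
  # distinct pairs never flagged
  set.seed(5)
  rnd <- tibble::tibble(
    chrom1 = "chrA", pos1 = sample.int(1e6, 1000), strand1 = "+",
    chrom2 = "chrA", pos2 = 2e6 + sample.int(1e6, 1000), strand2 = "+"
  )
  expect_equal(sum(dedup_pairs(rnd)$duplicate), 0)
})

test_that("deduplicated counts are order-independent", {
  s <- small_sim(seed = 21, n_pairs = 4000)
  ct1 <- extract_contacts(s$pairs, s$genome$map, s$genome$baits, s$genome$loci)
  set.seed(1)
  shuf <- s$pairs[sample.int(nrow(s$pairs)), ]
  ct2 <- extract_contacts(shuf, s$genome$map, s$genome$baits, s$genome$loci)
  expect_equal(ct1$stats, ct2$stats)
  expect_equal(ct1$counts, ct2$counts)
})

test_that("library accounting conserves every input pair", {
  s <- small_sim(seed = 13, n_pairs = 10000)
  ct <- extract_contacts(s$pairs, s$genome$map, s$genome$baits, s$genome$loci)
  st <- ct$stats
  expect_identical(st$raw_pairs,
                   st$unmapped + st$duplicates + st$off_target +
                     st$cis + st$trans)
  expect_identical(st$on_target, st$cis + st$trans)
  expect_identical(st$mapped, st$raw_pairs - st$unmapped)
  # duplicate removal matches the generator's emitted-duplicate count exactly
  expect_identical(st$duplicates, s$truth$n_duplicates)
  # 9 cis + 1 trans -> 90% cis
  expect_equal(
    extract_contacts(
      tibble::tibble(
        chrom1 = "chrA", pos1 = c(rep(5000, 9), 9000), strand1 = "+",
        chrom2 = c(rep("chrA", 9), "chrB"),
        pos2 = c(seq(17000, 17800, by = 100), 200), strand2 = "-"
      ), toy_map(), toy_baits(), toy_loci()
    )$stats$pct_cis, 90)
  # empty input: all stats zero
  e <- extract_contacts(
    tibble::tibble(chrom1 = character(), pos1 = numeric(), strand1 = character(),
                   chrom2 = character(), pos2 = numeric(), strand2 = character()),
    toy_map(), toy_baits(), toy_loci())
  expect_equal(e$stats$raw_pairs, 0)
  expect_equal(nrow(e$counts), 0)
})

test_that("pairs with an unmapped end are tallied and dropped", {
  p <- tibble::tibble(
    chrom1 = "chrA", pos1 = c(5100, 5100), strand1 = "+",
    chrom2 = "chrA", pos2 = c(18000, 18500), strand2 = "+",
    mapped1 = c(TRUE, TRUE), mapped2 = c(TRUE, FALSE)
  )
  ct <- extract_contacts(p, toy_map(), toy_baits(), toy_loci())
  expect_equal(ct$stats$unmapped, 1)
  expect_equal(ct$stats$cis, 1)
})

test_that("a pair anchored at both ends contributes to both bait profiles", {
  p <- tibble::tibble(chrom1 = "chrA", pos1 = 5100, strand1 = "+",
                      chrom2 = "chrA", pos2 = 9100, strand2 = "+")
  ct <- extract_contacts(p, toy_map(), toy_baits(), toy_loci())
  expect_equal(sort(ct$counts$bait), c("E2D", "E3D"))
  expect_equal(ct$stats$cis, 1)  # but the pair is counted once in stats
})
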