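# builds a contact-table-like counts tibble with given per-bait totals
counts_with_totals <- function(totals) {
  tibble::tibble(
    bait = names(totals), chrom = "c", frag_idx = 1L,
    start = 0, end = 100, count = as.integer(totals)
  )
}

fake_baits <- function(names_) {
  tibble::tibble(name = names_, locus = "l", chrom = "c",
                 site_index = seq_along(names_), side = "U",
                 start = seq_along(names_) * 1000,
                 end = seq_along(names_) * 1000 + 250,
                 site_pos = seq_along(names_) * 1000 + 250, flank = 250)
}

test_that("probe filter removes exactly floor(pct/100 * P) lowest probes", {
  totals <- setNames(1:10, paste0("E", sprintf("%02d", 1:10), "U"))
  qc <- probe_qc(counts_with_totals(totals), fake_baits(names(totals)), pct = 22)
  removed <- qc$bait[qc$status == "removed_low_efficiency"]
  expect_equal(length(removed), 2)  # floor(0.22 * 10)
  expect_setequal(removed, names(totals)[1:2])
  # pct 0 removes none
  qc0 <- probe_qc(counts_with_totals(totals), fake_baits(names(totals)), pct = 0)
  expect_true(all(qc0$status == "retained"))
  # ties broken by bait name ascending
  eq <- setNames(rep(5, 10), paste0("E", sprintf("%02d", 1:10), "U"))
  qce <- probe_qc(counts_with_totals(eq), fake_baits(names(eq)), pct = 22)
  expect_equal(qce$bait[qce$status == "removed_low_efficiency"],
               sort(names(eq))[1:2])
  # exact removal count across many P
  for (P in c(1, 3, 7, 22, 100)) {
    tt <- setNames(seq_len(P) * 10, paste0("E", sprintf("%03d", seq_len(P)), "U"))
    q <- probe_qc(counts_with_totals(tt), fake_baits(names(tt)), pct = 22)
    expect_equal(sum(q$status == "removed_low_efficiency"), floor(0.22 * P))
  }
})

test_that("repeat-overlapping probes are removed regardless of counts", {
  totals <- setNames(c(100, 200, 300), c("E1U", "E2U", "E3U"))
  baits <- fake_baits(names(totals))
  repeats <- tibble::tibble(chrom = "c", start = 2900, end = 3100)  # hits E3U
  qc <- probe_qc(counts_with_totals(totals), baits, pct = 0, repeats = repeats)
  expect_equal(qc$status[qc$bait == "E3U"], "removed_repeat")
  expect_true(all(qc$status[qc$bait != "E3U"] == "retained"))
})

test_that("median normalization gives the stated factors and identities", {
  totals <- setNames(c(10, 20, 30), c("E1U", "E2U", "E3U"))
  qc <- probe_qc(counts_with_totals(totals), fake_baits(names(totals)), pct = 0)
  expect_equal(sort(qc$factor, decreasing = TRUE), c(2, 1, 2 / 3),
               tolerance = 1e-12)
  # equal totals -> all factors 1
  eq <- setNames(rep(7, 5), paste0("E", 1:5, "U"))
  qeq <- probe_qc(counts_with_totals(eq), fake_baits(names(eq)), pct = 0)
  expect_true(all(qeq$factor == 1))
  # post-normalization per-probe totals all equal the retained median
  s <- small_sim(seed = 31, n_pairs = 8000)
  ct <- extract_contacts(s$pairs, s$genome$map, s$genome$baits, s$genome$loci)
  qcf <- probe_qc(ct, s$genome$baits)
  norm <- normalize_contacts(ct, qcf)
  med <- median(qcf$raw_total[qcf$status == "retained"])
  per_bait <- norm |> dplyr::group_by(bait) |>
    dplyr::summarise(total = sum(norm_count))
  expect_true(all(abs(per_bait$total - med) < 1e-9))
})

test_that("normalization is scale-equivariant", {
  totals <- setNames(c(12, 40, 28, 90), paste0("E", 1:4, "U"))
  cc <- counts_with_totals(totals)
  qc1 <- probe_qc(cc, fake_baits(names(totals)), pct = 0)
  cc3 <- cc |> dplyr::mutate(count = count * 3L)
  qc3 <- probe_qc(cc3, fake_baits(names(totals)), pct = 0)
  expect_equal(qc1$factor, qc3$factor)
  n1 <- normalize_contacts(cc, qc1)
  n3 <- normalize_contacts(cc3, qc3)
  expect_equal(n3$norm_count, 3 * n1$norm_count)
})

test_that("zero-total probes are removed with a warning before factors", {
  totals <- setNames(c(0, 20, 30), c("E1U", "E2U", "E3U"))
  expect_warning(
    qc <- probe_qc(counts_with_totals(totals), fake_baits(names(totals)),
                   pct = 0),
    "zero total")
  expect_equal(qc$status[qc$bait == "E1U"], "removed_low_efficiency")
  expect_equal(median(qc$raw_total[qc$status == "retained"]), 25)
  expect_warning(
    expect_warning(
      qc0 <- probe_qc(counts_with_totals(setNames(c(0, 0), c("E1U", "E2U"))),
                      fake_baits(c("E1U", "E2U")), pct = 0),
      "zero total"),
    "all probes removed")
  expect_true(all(qc0$status != "retained"))
})

test_that("bait-proximal masking flags window-overlapping fragments only", {
  map <- toy_map()
  baits <- toy_baits()
  ct <- extract_contacts(
    tibble::tibble(
      chrom1 = "chrA", pos1 = rep(5100, 3), strand1 = "+",
      chrom2 = "chrA", pos2 = c(5500, 16000, 19000), strand2 = c("+", "-", "+")
    ), map, baits, toy_loci())
  m <- mask_bait_proximal(ct$counts, map, baits, exclusion_bp = 2000)
  # partner fragment [5000,9000) is within 2 kb of the E2D site at 5000
  expect_true(all(m$masked[m$start == 5000]))
  # fragment [15000,20000) starts 10 kb away: unmasked
  expect_false(any(m$masked[m$start == 15000]))
  # masked entries are flagged, not deleted
  expect_equal(nrow(m), nrow(ct$counts))
  # exclusion 0 masks only the fragment starting at the bait site
  m0 <- mask_bait_proximal(ct$counts, map, baits, exclusion_bp = 0)
  expect_true(all(m0$masked[m0$start == 5000]))
  # masking never alters counts
  expect_equal(m$count, ct$counts$count)
})
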