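#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place. The
#' defaults are the parameters the method was designed with: 250 bp
#' informative-pair flank, window 1, 1000 permutations, top fifth percentile
#' candidate, FDR 0.01, lower-22-percentile probe removal, and a 25 kb
#' bait-proximal exclusion.
#'
#' @param flank Informative-pair / probe flank in bp.
#' @param window,n_perm,fdr,top_pct,seed See [sig_config()].
#' @param low_probe_pct Percentile of probes removed as low-efficiency.
#' @param bait_exclusion Bait-proximal exclusion half-width in bp.
#' @param min_counts Joint minimum-count filters reported for replicate
#'   reproducibility.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(flank = 250, window = 1L, n_perm = 1000L,
                            fdr = 0.01, top_pct = 5, low_probe_pct = 22,
                            bait_exclusion = 25000, min_counts = c(1L, 3L),
                            seed = 1L) {
  vals <- c(flank, window, n_perm, top_pct, bait_exclusion)
  if (any(vals <= 0)) abort("all pipeline parameters must be positive")
  if (fdr <= 0 || fdr >= 1) abort("`fdr` must be in (0, 1)")
  structure(list(flank = flank, window = as.integer(window),
                 n_perm = as.integer(n_perm), fdr = fdr, top_pct = top_pct,
                 low_probe_pct = low_probe_pct,
                 bait_exclusion = bait_exclusion, min_counts = min_counts,
                 seed = seed),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full capture-3C analysis
#'
#' Executes extract, probe QC and normalization, bait-proximal masking,
#' permutation interaction calling on the retained baits, and optional
#' epigenomic-track annotation of the significant fragments. Every
#' randomized stage is reproducible from (config, seed): two runs with the
#' same inputs write byte-identical files.
#'
#' @param pairs Pair table.
#' @param map A [restriction_map()].
#' @param baits Bait design table.
#' @param loci Target locus table.
#' @param config A [pipeline_config()].
#' @param tracks Optional named list of interval tibbles for annotation.
#' @param out_dir Optional output directory; when given, writes
#'   `stats.json`, `probe_qc.tsv`, `contacts.tsv`, `normalized.tsv`,
#'   `significant.tsv` and `significant.bedpe`.
#' @return A `c3c_report` list: `stats`, `qc`, `normalized` (masked,
#'   normalized contacts), `calls` (a `sig_calls`), `significant` (tibble of
#'   significant rows with 1-based inclusive `start1` positions for human
#'   reading) and `annotated` (when tracks were given).
#' @export
run_pipeline <- function(pairs, map, baits, loci, config = pipeline_config(),
                         tracks = NULL, out_dir = NULL) {
  ct <- .stage("extract",
               extract_contacts(pairs, map, baits, loci, flank = config$flank))
  qc <- .stage("normalize", probe_qc(ct, baits, pct = config$low_probe_pct))
  norm <- .stage("normalize", normalize_contacts(ct, qc))
  norm <- .stage("normalize",
                 mask_bait_proximal(norm, map, baits,
                                    exclusion_bp = config$bait_exclusion))
  retained <- baits[baits$name %in% qc$bait[qc$status == "retained"], ]
  scfg <- sig_config(window = config$window, n_perm = config$n_perm,
                     fdr = config$fdr, top_pct = config$top_pct,
                     seed = config$seed)
  calls <- .stage("call",
                  call_interactions(ct, map, retained, scfg,
                                    exclusion_bp = config$bait_exclusion))
  sig <- calls$table |>
    filter(significant) |>
    mutate(start1 = start + 1)  # 1-based inclusive for human-facing tables
  ann <- NULL
  if (!is.null(tracks) && nrow(sig)) {
    ann <- .stage("annotate", annotate_overlap(sig, tracks))
  }
  report <- structure(list(stats = ct$stats, qc = qc, normalized = norm,
                           calls = calls, significant = sig, annotated = ann,
                           config = config),
                      class = "c3c_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stats_json(ct$stats, file.path(out_dir, "stats.json"))
    readr::write_tsv(qc, file.path(out_dir, "probe_qc.tsv"))
    write_contacts(ct, file.path(out_dir, "contacts.tsv"))
    readr::write_tsv(norm, file.path(out_dir, "normalized.tsv"))
    readr::write_tsv(sig, file.path(out_dir, "significant.tsv"))
    write_bedpe(sig, baits, file.path(out_dir, "significant.bedpe"))
  }
  report
}

#' @export
print.c3c_report <- function(x, ...) {
  cat("<c3c_report>\n")
  print(x$stats)
  cat(nrow(x$significant), "significant bait-fragment interactions\n")
  invisible(x)
}
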