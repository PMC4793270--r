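#' Position weight matrix
#'
#' Builds a PWM from a 4 x W count or probability matrix (rows A, C, G, T).
#' Count matrices are converted to probabilities with a pseudocount split
#' according to the background: `p = (count + pc * bg) / (total + pc)`.
#' Each column of the resulting probability matrix must sum to 1 (within
#' 1e-9).
#'
#' @param mat Numeric matrix, 4 rows (A, C, G, T) by motif width columns.
#'   Probabilities (columns summing to 1) or raw counts.
#' @param pseudocount Pseudocount added per column when converting counts.
#' @param background Base composition of the genomic background, length-4
#'   probability vector (A, C, G, T).
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, pseudocount = 0.8, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("`mat` must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) abort("motif width must be >= 1")
  if (any(mat < 0)) abort("negative matrix entries")
  if (abs(sum(background) - 1) > 1e-9 || length(background) != 4) {
    abort("`background` must be 4 probabilities summing to 1")
  }
  rownames(mat) <- c("A", "C", "G", "T")
  colsums <- colSums(mat)
  if (all(abs(colsums - 1) < 1e-9)) {
    prob <- mat
  } else {
    prob <- sweep(mat + pseudocount * background, 2, colsums + pseudocount, "/")
  }
  if (any(abs(colSums(prob) - 1) > 1e-9)) {
    abort("PWM columns do not sum to 1 after pseudocount")
  }
  structure(list(prob = prob, width = ncol(prob),
                 pseudocount = pseudocount,
                 background = setNames(background, c("A", "C", "G", "T"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width", x$width, "\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' Read a JASPAR-format matrix file
#'
#' Accepts the standard JASPAR text layout: an optional `>ID name` header
#' followed by four rows, either bare numbers or `A [ ... ]` bracketed rows
#' in A, C, G, T order. Column count totals must agree across rows within a
#' relative tolerance (count matrices describe one set of aligned sites).
#'
#' @param path Path to the matrix file.
#' @param pseudocount,background Passed to [pwm()].
#' @param tol Maximum relative deviation of a column total from the median
#'   column total.
#' @return A [pwm()] object.
#' @export
read_jaspar <- function(path, pseudocount = 0.8, background = rep(0.25, 4),
                        tol = 0.1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), ">")]
  if (length(lines) != 4) abort("expected 4 matrix rows (A, C, G, T)")
  parse_row <- function(ln) {
    ln <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?", "", ln)
    ln <- gsub("\\]", "", ln)
    as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
  }
  rows <- lapply(lines, parse_row)
  if (length(unique(lengths(rows))) != 1) abort("matrix rows have unequal widths")
  mat <- do.call(rbind, rows)
  colsums <- colSums(mat)
  if (!all(abs(colsums - 1) < 1e-9)) {
    med <- median(colsums)
    if (med <= 0 || any(abs(colsums - med) > tol * med)) {
      abort("inconsistent JASPAR column totals (beyond tolerance)")
    }
  }
  pwm(mat, pseudocount = pseudocount, background = background)
}

.revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Log-odds score of sequence windows against a PWM
#'
#' `score = sum_i log2(p_i(base_i) / background(base_i))`. Windows containing
#' `N` score `-Inf`.
#'
#' @param x A [pwm()].
#' @param windows Character vector of sequences, each exactly the motif
#'   width.
#' @return Numeric vector of log2-odds scores.
#' @export
pwm_score <- function(x, windows) {
  stopifnot(inherits(x, "pwm"))
  windows <- toupper(windows)
  if (any(nchar(windows) != x$width)) abort("window length must equal PWM width")
  lo <- log2(x$prob / x$background)
  vapply(windows, function(wd) {
    b <- strsplit(wd, "")[[1]]
    i <- match(b, rownames(x$prob))
    if (anyNA(i)) return(-Inf)
    sum(lo[cbind(i, seq_along(i))])
  }, 1, USE.NAMES = FALSE)
}

#' Allele-specific motif disruption score
#'
#' For each allele substituted at the SNP position, all windows covering the
#' SNP on both strands are scored and the maximum (best-affinity) score
#' retained; `delta = score1 - score2` quantifies the predicted binding
#' disruption of allele 2 relative to allele 1.
#'
#' @param x A [pwm()].
#' @param context Nucleotide string around the SNP (length >= motif width).
#' @param snp_pos 1-based position of the SNP within `context`.
#' @param allele1,allele2 Single bases in A, C, G, T.
#' @return One-row tibble with `score1`, `score2`, `delta`.
#' @export
pwm_allele_delta <- function(x, context, snp_pos, allele1, allele2) {
  stopifnot(inherits(x, "pwm"))
  context <- toupper(context)
  W <- x$width
  n <- nchar(context)
  if (n < W) abort("context shorter than PWM width")
  if (snp_pos < 1 || snp_pos > n) abort("`snp_pos` outside context")
  for (a in c(allele1, allele2)) {
    if (!toupper(a) %in% c("A", "C", "G", "T")) {
      abort(paste0("invalid allele: ", a))
    }
  }
  starts <- max(1, snp_pos - W + 1):min(snp_pos, n - W + 1)
  if (!length(starts)) abort("no scanning window covers the SNP")
  best <- function(allele) {
    s <- context
    substr(s, snp_pos, snp_pos) <- toupper(allele)
    wins <- substring(s, starts, starts + W - 1)
    max(pwm_score(x, wins), pwm_score(x, .revcomp(wins)))
  }
  s1 <- best(allele1)
  s2 <- best(allele2)
  tibble(score1 = s1, score2 = s2, delta = s1 - s2)
}
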