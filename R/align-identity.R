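# Local sequence similarity between candidate homologous contigs, with
# BLASTn-tabular semantics: percent identity = identical columns / alignment
# columns * 100, over the best-scoring local alignment. Two engines sit
# behind one interface: an internal affine-gap Smith-Waterman (exact DP,
# used up to a cell-count cap) and a blastn subprocess for long pairs.
# Scoring follows the classic BLASTn-like scheme: match +2, mismatch -3,
# gap of length L costs open + L * extend (open 5, extend 2).

#' Percent identity of the best local alignment
#'
#' @param seq_a,seq_b DNA sequences (non-empty character scalars).
#' @param method "auto" (internal DP up to `max_cells` DP cells, blastn
#'   beyond), "sw" (force internal), or "blastn" (force subprocess).
#' @param match,mismatch,gap_open,gap_ext internal-DP scoring parameters.
#' @param max_cells cell-count cap for the internal DP under "auto".
#' @return list with pct_identical (0..100), alignment_length (columns,
#'   including gap columns), score (internal DP only, else NA), method.
#'   If nothing aligns with positive score, pct_identical = 0 and
#'   alignment_length = 0.
#' @details Internal-DP tie-breaks are fixed: the best cell is the first
#'   score maximum in column-major order (smallest position in `seq_b`, then
#'   in `seq_a`); traceback prefers diagonal over vertical over horizontal
#'   moves and ends gaps as early as possible. `N` mismatches every base.
#' @export
pairwise_identity <- function(seq_a, seq_b, method = c("auto", "sw", "blastn"),
                              match = 2, mismatch = -3, gap_open = 5,
                              gap_ext = 2, max_cells = 4e6) {
  method <- match.arg(method)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  # identity is a symmetric quantity but alignment tie-breaks are not:
  # canonicalise the argument order so swapped inputs give identical output
  if (seq_b < seq_a) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  n <- nchar(seq_a); m <- nchar(seq_b)
  if (method == "auto")
    method <- if (as.double(n) * m <= max_cells) "sw" else "blastn"
  if (method == "sw") {
    al <- sw_align(seq_a, seq_b, match, mismatch, gap_open, gap_ext)
    if (al$score <= 0)
      return(list(pct_identical = 0, alignment_length = 0L, score = al$score,
                  method = "sw"))
    list(pct_identical = 100 * al$n_ident / al$align_len,
         alignment_length = al$align_len, score = al$score, method = "sw")
  } else {
    hit <- blastn_best_hit(seq_a, seq_b)
    if (is.null(hit))
      return(list(pct_identical = 0, alignment_length = 0L, score = NA_real_,
                  method = "blastn"))
    list(pct_identical = hit$pident, alignment_length = hit$length,
         score = NA_real_, method = "blastn")
  }
}

#' Affine-gap Smith-Waterman local alignment
#'
#' Row-vectorised dynamic program with full H/E/F matrices retained for
#' traceback; the horizontal-gap matrix is computed with a running-maximum
#' transform (chaining one horizontal gap into another is always dominated
#' by a single longer gap, so the transform is exact). A gap of length L
#' costs `gap_open + L * gap_ext`.
#'
#' @param seq_a,seq_b DNA sequences.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @return list: score, n_ident (identical columns), align_len (alignment
#'   columns including gaps), end_a/end_b (1-based alignment end positions).
#' @export
sw_align <- function(seq_a, seq_b, match = 2, mismatch = -3, gap_open = 5,
                     gap_ext = 2) {
  av <- utf8ToInt(seq_a); bv <- utf8ToInt(seq_b)
  n <- length(av); m <- length(bv)
  NINF <- -1e18
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NINF, n + 1L, m + 1L)   # gap in seq_a (move left)
  F <- matrix(NINF, n + 1L, m + 1L)   # gap in seq_b (move up)
  ncode <- utf8ToInt("N")
  jj <- seq_len(m)
  ext_j <- gap_ext * jj
  for (i in seq_len(n)) {
    subs <- ifelse(bv == av[i] & av[i] != ncode & bv != ncode, match, mismatch)
    Fi <- pmax(H[i, jj + 1L] - gap_open - gap_ext, F[i, jj + 1L] - gap_ext)
    Hp <- pmax(H[i, jj] + subs, Fi, 0)
    P <- cummax(c(H[i + 1L, 1L], Hp[-m] + ext_j[-m]))
    Ei <- P - gap_open - gap_ext * jj
    F[i + 1L, jj + 1L] <- Fi
    E[i + 1L, jj + 1L] <- Ei
    H[i + 1L, jj + 1L] <- pmax(Hp, Ei)
  }
  best <- which.max(H)   # column-major: smallest j, then smallest i
  score <- H[best]
  if (score <= 0)
    return(list(score = 0, n_ident = 0L, align_len = 0L,
                end_a = 0L, end_b = 0L))
  i <- (best - 1L) %% (n + 1L)
  j <- (best - 1L) %/% (n + 1L)
  end_a <- i; end_b <- j
  n_ident <- 0L; align_len <- 0L
  state <- "H"
  while (i > 0L || j > 0L) {
    if (state == "H") {
      if (H[i + 1L, j + 1L] == 0) break
      if (i > 0L && j > 0L) {
        s <- if (av[i] == bv[j] && av[i] != ncode) match else mismatch
        if (H[i + 1L, j + 1L] == H[i, j] + s) {
          align_len <- align_len + 1L
          if (av[i] == bv[j] && av[i] != ncode) n_ident <- n_ident + 1L
          i <- i - 1L; j <- j - 1L
          next
        }
      }
      if (H[i + 1L, j + 1L] == F[i + 1L, j + 1L]) state <- "F"
      else state <- "E"
    } else if (state == "F") {
      align_len <- align_len + 1L
      from_h <- H[i, j + 1L] - gap_open - gap_ext
      if (F[i + 1L, j + 1L] == from_h) state <- "H"   # end gap asap
      i <- i - 1L
    } else {
      align_len <- align_len + 1L
      from_h <- H[i + 1L, j] - gap_open - gap_ext
      if (E[i + 1L, j + 1L] == from_h) state <- "H"
      j <- j - 1L
    }
  }
  list(score = score, n_ident = n_ident, align_len = align_len,
       end_a = end_a, end_b = end_b)
}

# best blastn hit (by bitscore) between two sequences; NULL when no hit
blastn_best_hit <- function(seq_a, seq_b) {
  exe <- Sys.which("blastn")
  if (!nzchar(exe))
    stop("blastn executable not found; required for long sequence pairs")
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)))
  writeLines(c(">q", seq_a), qf)
  writeLines(c(">s", seq_b), sf)
  out <- suppressWarnings(system2(
    exe, c("-query", qf, "-subject", sf, "-task", "blastn",
           "-outfmt", shQuote("6 pident length bitscore")),
    stdout = TRUE, stderr = FALSE))
  if (!length(out)) return(NULL)
  f <- strsplit(out, "\t", fixed = TRUE)
  pident <- vapply(f, function(x) as.numeric(x[1]), numeric(1))
  len <- vapply(f, function(x) as.integer(x[2]), integer(1))
  bits <- vapply(f, function(x) as.numeric(x[3]), numeric(1))
  k <- which.max(bits)
  list(pident = pident[k], length = len[k])
}
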