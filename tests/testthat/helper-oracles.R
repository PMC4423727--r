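# Independent oracles and fixture builders shared across the test files.

# ---- scalar Smith-Waterman oracle ------------------------------------------
# Plain triple-loop affine-gap local alignment with the same documented
# conventions as the package aligner: match/mismatch substitution, gap of
# length L costs open + L*ext, best cell = first maximum in column-major
# order, traceback prefers diagonal > vertical > horizontal and ends gaps as
# early as possible. Written independently of the package implementation.
oracle_sw <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  best <- which.max(H)
  score <- H[best]
  if (score <= 0) return(list(score = 0, n_ident = 0L, align_len = 0L))
  i <- (best - 1) %% (n + 1)
  j <- (best - 1) %/% (n + 1)
  nid <- 0L; alen <- 0L
  state <- "H"
  while (i > 0 || j > 0) {
    if (state == "H") {
      if (H[i + 1, j + 1] == 0) break
      moved <- FALSE
      if (i > 0 && j > 0) {
        s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
        if (H[i + 1, j + 1] == H[i, j] + s) {
          alen <- alen + 1L
          if (av[i] == bv[j] && av[i] != "N") nid <- nid + 1L
          i <- i - 1; j <- j - 1
          moved <- TRUE
        }
      }
      if (!moved) {
        if (H[i + 1, j + 1] == F[i + 1, j + 1]) state <- "F" else state <- "E"
      }
    } else if (state == "F") {
      alen <- alen + 1L
      if (F[i + 1, j + 1] == H[i, j + 1] - open - ext) state <- "H"
      i <- i - 1
    } else {
      alen <- alen + 1L
      if (E[i + 1, j + 1] == H[i + 1, j] - open - ext) state <- "H"
      j <- j - 1
    }
  }
  list(score = score, n_ident = nid, align_len = alen)
}

# ---- brute-force perfect-bubble oracle -------------------------------------
# Literal application of the textual definition over all ordered 4-tuples:
# a and b each with a single candidate scaffolding to common flanks in both
# directions, flanks consistently oriented with no conflicting scaffoldings.
oracle_perfect_bubbles <- function(graph) {
  ed <- graph$edges[!graph$edges$excluded]
  if (length(graph$repeats))
    ed <- ed[!(ed$c_a %in% graph$repeats | ed$c_b %in% graph$repeats), ]
  ids <- graph$contigs$id
  inc <- function(c, e) {
    hit <- (ed$c_a == c & ed$e_a == e) | (ed$c_b == c & ed$e_b == e)
    ed[hit, , drop = FALSE]
  }
  partner_of <- function(row, c, e) {
    if (row$c_a == c && row$e_a == e) c(row$c_b, row$e_b)
    else c(row$c_a, row$e_a)
  }
  found <- character()
  out <- list()
  for (a in ids) {
    a5 <- inc(a, "5p"); a3 <- inc(a, "3p")
    if (nrow(a5) != 1 || nrow(a3) != 1) next
    p5 <- partner_of(a5[1, ], a, "5p")
    p3 <- partner_of(a3[1, ], a, "3p")
    c1 <- p5[1]; e1 <- p5[2]; c2 <- p3[1]; e2 <- p3[2]
    if (c1 == c2) next
    for (b in ids) {
      if (b == a || b %in% c(c1, c2) || a %in% c(c1, c2)) next
      b5 <- inc(b, "5p"); b3 <- inc(b, "3p")
      if (nrow(b5) != 1 || nrow(b3) != 1) next
      q5 <- partner_of(b5[1, ], b, "5p")
      q3 <- partner_of(b3[1, ], b, "3p")
      ok <- (identical(q5, c(c1, e1)) && identical(q3, c(c2, e2))) ||
        (identical(q5, c(c2, e2)) && identical(q3, c(c1, e1)))
      if (!ok) next
      # flank purity: exactly the two bubble edges on each facing flank end
      if (nrow(inc(c1, e1)) != 2 || nrow(inc(c2, e2)) != 2) next
      key <- paste(sort(c(a, b)), collapse = "|")
      fkey <- paste(sort(c(paste0(c1, ":", e1), paste0(c2, ":", e2))),
                    collapse = "|")
      k <- paste(key, fkey)
      if (k %in% found) next
      found <- c(found, k)
      out[[length(out) + 1L]] <- data.frame(
        a = sort(c(a, b))[1], b = sort(c(a, b))[2],
        c1 = c1, c2 = c2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(), c1 = character(),
                      c2 = character()))
  }
  unique(do.call(rbind, out))
}

# canonical comparable keys for bubble tables
bubble_keyset <- function(tab) {
  if (!nrow(tab)) return(character())
  sort(paste(pmin(tab$a, tab$b), pmax(tab$a, tab$b),
             pmin(tab$c1, tab$c2), pmax(tab$c1, tab$c2)))
}

# ---- random fixtures --------------------------------------------------------
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_test_graph <- function(n_vertices, n_edges) {
  ids <- sprintf("v%02d", seq_len(n_vertices))
  lens <- stats::setNames(rep(500L, n_vertices), ids)
  rows <- list()
  seen <- character()
  guard <- 0L
  while (length(rows) < n_edges && guard < 40L * n_edges) {
    guard <- guard + 1L
    v <- sample(ids, 2L)
    e <- sample(c("5p", "3p"), 2L, replace = TRUE)
    key <- paste(min(v), max(v), if (v[1] < v[2]) paste(e, collapse = "")
                 else paste(rev(e), collapse = ""))
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1L]] <- data.frame(
      c_a = v[1], e_a = e[1], c_b = v[2], e_b = e[2],
      weight = sample(1:9, 1L), gap = round(stats::runif(1, -50, 300)),
      stringsAsFactors = FALSE)
  }
  scaffold_graph(do.call(rbind, rows), lens)
}

# ---- cached small universe for cross-file reuse ----------------------------
.test_cache <- new.env(parent = emptyenv())

get_small_universe <- function() {
  if (is.null(.test_cache$uni)) {
    .test_cache$uni <- simulate_universe(length = 60000, seed = 42)
  }
  .test_cache$uni
}

# the full-scale seeded benchmark run shared by the acceptance tests:
# 500-kb diploid at heterozygosity 0.04, error-free 75-bp pairs at 40x per
# haplotype from 400-bp and 1000-bp libraries
get_benchmark_run <- function() {
  if (is.null(.test_cache$bench)) {
    u <- simulate_universe(length = 500000, seed = 101)
    aln <- lapply(u$assignments, function(a) {
      x <- a[!is.na(a$contig), ]
      data.table::setDT(x)
      x[, mult := .N, by = "read_id"]
      x
    })
    libs <- data.frame(name = names(aln),
                       mean_insert = u$libraries$mean_insert,
                       rank = u$libraries$rank, format = "sam",
                       stringsAsFactors = FALSE)
    libs$files <- replicate(nrow(libs), character(), simplify = FALSE)
    res <- scaffold_diploid(u$truth$contigs, libs, depths = u$depths,
                            alignments = aln, seed = 1)
    .test_cache$bench <- list(universe = u, result = res,
                              eval = evaluate_scaffolding(res, u))
  }
  .test_cache$bench
}
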