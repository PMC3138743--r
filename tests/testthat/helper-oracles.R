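# Independent oracles: deliberately naive re-implementations used only to
# cross-check package results.

# windowed weighted mean by direct loops over every cell and window offset
oracle_regional <- function(scores, weights) {
  nr <- nrow(scores); nc <- ncol(scores)
  h <- (nrow(weights) - 1L) %/% 2L
  out <- matrix(NA_real_, nr, nc, dimnames = dimnames(scores))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(scores[i, j])) next
    num <- 0; den <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      v <- scores[ii, jj]
      w <- weights[di + h + 1L, dj + h + 1L]
      if (!is.na(v) && w > 0) { num <- num + w * v; den <- den + w }
    }
    out[i, j] <- num / den
  }
  out
}

# exhaustive global alignment score with affine gaps: plain recursion over
# every monotone path (feasible only for short strings)
oracle_align_score <- function(a, b, score_fun, gap_open, gap_ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, score_fun(A[i], B[j]) + rec(i + 1L, j + 1L, "m"))
    if (i <= length(A))
      best <- max(best, -(if (last == "a") gap_ext else gap_open) +
                    rec(i + 1L, j, "a"))
    if (j <= length(B))
      best <- max(best, -(if (last == "b") gap_ext else gap_open) +
                    rec(i, j + 1L, "b"))
    best
  }
  rec(1L, 1L, "m")
}

# score of a given pairwise alignment under the same affine model
score_pair_alignment <- function(sa, sb, score_fun, gap_open, gap_ext) {
  A <- strsplit(sa, "")[[1]]; B <- strsplit(sb, "")[[1]]
  stopifnot(length(A) == length(B))
  tot <- 0; last <- "m"
  for (k in seq_along(A)) {
    if (A[k] != "-" && B[k] != "-") {
      tot <- tot + score_fun(A[k], B[k]); last <- "m"
    } else if (A[k] == "-") {
      tot <- tot - (if (last == "a") gap_ext else gap_open); last <- "a"
    } else {
      tot <- tot - (if (last == "b") gap_ext else gap_open); last <- "b"
    }
  }
  tot
}

random_masked_grid <- function(nr, nc, mask_frac = 0.1) {
  s <- matrix(stats::runif(nr * nc), nr, nc,
              dimnames = list(seq_len(nr), seq_len(nc)))
  s[stats::runif(nr * nc) < mask_frac] <- NA
  if (all(is.na(s))) s[1, 1] <- 0.5
  s
}

as_grid <- function(scores, mode = "weighted") {
  structure(list(scores = scores, mode = mode, matrix_id = "test",
                 gap_policy = "score"),
            class = "rcm_grid")
}
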