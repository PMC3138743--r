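# Per-cell conservation: mean pairwise substitution score over all
# unordered pairs of family members at each grid cell, in raw
# (substitution-matrix units) or weighted (normalized to [0,1]) mode.

# pair-score lookup table over the matrix alphabet plus '-'
.pair_score_table <- function(matrix, mode, gap_policy) {
  ab <- rownames(matrix$entries)
  full <- c(ab, "-")
  W <- matrix(NA_real_, length(full), length(full), dimnames = list(full, full))
  if (mode == "raw") {
    W[ab, ab] <- matrix$entries
    gapval <- if (gap_policy == "score") matrix$global_min else NA_real_
  } else {
    selfs <- diag(matrix$entries)
    denom <- outer(selfs, selfs, pmin) - matrix$global_min
    w <- (matrix$entries - matrix$global_min) / denom
    w[denom <= 0] <- 0
    W[ab, ab] <- pmin(pmax(w, 0), 1)
    gapval <- if (gap_policy == "score") 0 else NA_real_
  }
  W["-", ] <- gapval
  W[, "-"] <- gapval
  W
}

.canon_symbol <- function(s, matrix) {
  s <- toupper(s)
  known <- c(rownames(matrix$entries), "-")
  ifelse(s %in% known, s, if ("X" %in% rownames(matrix$entries)) "X"
         else stop("unknown residue and no X entry in matrix"))
}

#' Conservation score of one grid cell
#'
#' Mean over all unordered pairs of the symbols (one per family member) of
#' either the raw substitution score or the normalized pairwise score.
#' Under the default gap policy (`"score"`) a pair involving a gap scores
#' the matrix minimum (raw) or 0 (weighted); with `"exclude"` such pairs
#' are dropped from the average.
#'
#' @param symbols Character vector of >= 2 residues/gaps (`"-"`).
#' @param matrix An [rcm_matrix()].
#' @param mode `"weighted"` (default) or `"raw"`.
#' @param gap_policy `"score"` or `"exclude"`.
#' @return Numeric score (`NA` if every pair was excluded).
#' @examples
#' cell_conservation(c("L", "L", "I"))  # (1 + 0.75 + 0.75)/3
#' @export
cell_conservation <- function(symbols, matrix = rcm_matrix(),
                              mode = c("weighted", "raw"),
                              gap_policy = c("score", "exclude")) {
  mode <- match.arg(mode)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(matrix, "rcm_submat"))
  if (length(symbols) < 2L) stop("a cell needs at least two symbols")
  W <- .pair_score_table(matrix, mode, gap_policy)
  s <- .canon_symbol(symbols, matrix)
  pr <- utils::combn(length(s), 2L)
  mean(W[cbind(s[pr[1, ]], s[pr[2, ]])], na.rm = (gap_policy == "exclude"))
}

#' Score the full conservation grid
#'
#' For each unmasked cell of the reference grid, gathers the alignment
#' column's symbols across all family members and averages the pairwise
#' scores. Masked cells (repeat holes) stay masked. The result is
#' independent of the order of family members.
#'
#' @param alignment `"lrr_alignment"`.
#' @param cellmap Result of [map_cells_to_columns()].
#' @param matrix An [rcm_matrix()] (or id).
#' @inheritParams cell_conservation
#' @return Object of class `"rcm_grid"`: list with `scores` (repeats x
#'   variable-positions numeric matrix, `NA` = masked), `mode`,
#'   `matrix_id`, `gap_policy`.
#' @export
score_grid <- function(alignment, cellmap, matrix = rcm_matrix(),
                       mode = c("weighted", "raw"),
                       gap_policy = c("score", "exclude")) {
  mode <- match.arg(mode)
  gap_policy <- match.arg(gap_policy)
  if (!inherits(matrix, "rcm_submat")) matrix <- rcm_matrix(matrix)
  stopifnot(inherits(alignment, "lrr_alignment"), is.matrix(cellmap))
  W <- .pair_score_table(matrix, mode, gap_policy)
  chm <- do.call(rbind, lapply(alignment$aligned, .split1))  # members x cols
  chm[] <- .canon_symbol(chm, matrix)
  pr <- utils::combn(nrow(chm), 2L)
  scores <- matrix(NA_real_, nrow(cellmap), ncol(cellmap),
                   dimnames = dimnames(cellmap))
  for (k in which(!is.na(cellmap))) {
    syms <- chm[, cellmap[k]]
    scores[k] <- mean(W[cbind(syms[pr[1, ]], syms[pr[2, ]])],
                      na.rm = (gap_policy == "exclude"))
  }
  structure(list(scores = scores, mode = mode, matrix_id = matrix$matrix_id,
                 gap_policy = gap_policy),
            class = "rcm_grid")
}

#' @export
print.rcm_grid <- function(x, ...) {
  cat("RCM ", x$mode, " grid: ", nrow(x$scores), " repeats x ",
      ncol(x$scores), " variable positions (",
      sum(is.na(x$scores)), " masked)\n", sep = "")
  if (!is.null(x$matrix_id)) cat("  matrix: ", x$matrix_id, "\n", sep = "")
  invisible(x)
}
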