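# Regional conservation: center-weighted sliding-window smoothing of the
# cell-score grid — the quantity reported on the final map.

#' Build a sliding-window weight kernel
#'
#' The default kernel covers 25 cells spanning 5 repeats and weights by
#' Chebyshev ring distance from the center (halving outward: 4 at the
#' center, 2 on the first ring, 1 on the second), a balance between the
#' over-smoothing of a uniform window and the no-smoothing limit of a
#' center-only window.
#'
#' @param preset `"default"`, `"uniform"`, `"center_only"` or `"gaussian"`.
#' @param size Odd window edge length; default 5.
#' @param sigma Gaussian standard deviation in cells (gaussian preset only).
#' @return Object of class `"rcm_kernel"`: list with `preset`, `size`,
#'   `weights` (size x size, non-negative, center strictly positive).
#' @examples
#' sum(make_kernel()$weights)  # 36 = 4 + 8*2 + 16*1
#' @export
make_kernel <- function(preset = c("default", "uniform", "center_only", "gaussian"),
                        size = 5L, sigma = 1) {
  preset <- match.arg(preset)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("kernel size must be an odd integer >= 1")
  h <- (size - 1L) %/% 2L
  d <- outer(abs(seq(-h, h)), abs(seq(-h, h)), pmax)   # Chebyshev distance
  w <- switch(preset,
    default = 2 ^ (h - d),
    uniform = matrix(1, size, size),
    center_only = { z <- matrix(0, size, size); z[h + 1L, h + 1L] <- 1; z },
    gaussian = {
      if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
      dr2 <- outer(seq(-h, h)^2, seq(-h, h)^2, `+`)
      exp(-dr2 / (2 * sigma^2))
    })
  structure(list(preset = preset, size = size,
                 sigma = if (preset == "gaussian") sigma else NULL,
                 weights = w),
            class = "rcm_kernel")
}

#' @export
print.rcm_kernel <- function(x, ...) {
  cat("RCM window kernel '", x$preset, "' (", x$size, "x", x$size, ")\n",
      sep = "")
  print(x$weights)
  invisible(x)
}

#' Regional conservation map
#'
#' Slides the kernel over the cell-score grid. For each unmasked cell the
#' regional score is the weighted mean of the in-bounds, unmasked cell
#' scores under the window (truncated-window renormalization, so border
#' repeats and cells next to holes are still scored). Cells whose center is
#' masked stay masked.
#'
#' @param grid An `"rcm_grid"` from [score_grid()].
#' @param kernel An [make_kernel()] kernel.
#' @param edge_policy Only `"renormalize"` is implemented.
#' @return An `"rcm_grid"` with `mode = "regional"` and the kernel recorded.
#' @export
regional_map <- function(grid, kernel = make_kernel(),
                         edge_policy = "renormalize") {
  stopifnot(inherits(grid, "rcm_grid"), inherits(kernel, "rcm_kernel"))
  edge_policy <- match.arg(edge_policy, "renormalize")
  s <- grid$scores
  nr <- nrow(s); nc <- ncol(s)
  if (!any(!is.na(s))) stop("grid has no unmasked cells")
  if (kernel$size > 2L * nr && kernel$size > 2L * nc)
    warning("kernel (", kernel$size, "x", kernel$size,
            ") is larger than twice the grid in both dimensions")
  h <- (kernel$size - 1L) %/% 2L
  out <- matrix(NA_real_, nr, nc, dimnames = dimnames(s))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(s[i, j])) next
    ri <- max(1L, i - h):min(nr, i + h)
    rj <- max(1L, j - h):min(nc, j + h)
    w <- kernel$weights[ri - i + h + 1L, rj - j + h + 1L, drop = FALSE]
    v <- s[ri, rj, drop = FALSE]
    ok <- !is.na(v) & w > 0
    out[i, j] <- sum(w[ok] * v[ok]) / sum(w[ok])
  }
  structure(list(scores = out, mode = "regional",
                 matrix_id = grid$matrix_id, gap_policy = grid$gap_policy,
                 kernel = kernel, cell_mode = grid$mode),
            class = "rcm_grid")
}

#' Rank grid cells by score
#'
#' Descending for conserved-site prediction; ascending in divergence mode
#' (paralog maps read for diversified specificity). Ties are broken by
#' (repeat, column) position for determinism.
#'
#' @param map An `"rcm_grid"`.
#' @param direction `"conserved"` (default) or `"divergent"`.
#' @return data.frame with `repeat_index`, `motif_position`, `score`,
#'   `rank`, one row per unmasked cell, in rank order.
#' @export
rank_cells <- function(map, direction = c("conserved", "divergent")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "rcm_grid"))
  s <- map$scores
  idx <- which(!is.na(s), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("map has no unmasked cells")
  vals <- s[idx]
  key <- if (direction == "conserved") -vals else vals
  ord <- order(key, idx[, 1], idx[, 2])
  mp <- colnames(s)
  data.frame(
    repeat_index = as.integer(rownames(s)[idx[ord, 1]]),
    motif_position = as.integer(mp[idx[ord, 2]]),
    score = vals[ord],
    rank = seq_along(ord)
  )
}
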