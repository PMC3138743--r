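test_that("kernel presets have the stated shapes and weights", {
  k <- make_kernel()
  expect_equal(k$size, 5L)
  expect_equal(sum(k$weights > 0), 25L)
  expect_equal(sum(k$weights), 36)            # 4 + 8*2 + 16*1
  expect_equal(k$weights[3, 3], 4)
  expect_true(all(k$weights[3, 3] >= k$weights))

  u <- make_kernel("uniform")
  expect_true(all(u$weights == 1))
  co <- make_kernel("center_only")
  expect_equal(sum(co$weights > 0), 1L)
  expect_gt(co$weights[3, 3], 0)
  g <- make_kernel("gaussian", sigma = 1.2)
  expect_equal(g$weights[3, 3], 1)
  expect_true(all(diff(g$weights[3, 3:5]) < 0))

  expect_error(make_kernel(size = 4), "odd")
  expect_error(make_kernel("gaussian", sigma = 0), "positive")
})

test_that("a constant grid smooths to the same constant under any kernel", {
  s <- matrix(0.37, 8, 14, dimnames = list(1:8, 1:14))
  for (preset in c("default", "uniform", "center_only", "gaussian")) {
    rm_ <- regional_map(as_grid(s), make_kernel(preset))
    expect_equal(rm_$scores, s, tolerance = 1e-12)
  }
})

test_that("truncated uniform windows renormalize over surviving cells", {
  s <- matrix(0, 10, 10, dimnames = list(1:10, 1:10))
  g <- as_grid(s)
  g$scores[5, 5] <- 1
  rm_ <- regional_map(g, make_kernel("uniform"))
  expect_equal(rm_$scores[5, 5], 1 / 25)
  g2 <- as_grid(matrix(0, 10, 10, dimnames = list(1:10, 1:10)))
  g2$scores[1, 1] <- 1
  rm2 <- regional_map(g2, make_kernel("uniform"))
  expect_equal(rm2$scores[1, 1], 1 / 9)        # 3x3 surviving window
})

test_that("regional maps equal the brute-force window oracle", {
  set.seed(97)
  for (rep in 1:30) {
    nr <- sample(5:40, 1); nc <- sample(5:14, 1)
    s <- random_masked_grid(nr, nc)
    for (preset in c("uniform", "default")) {
      k <- make_kernel(preset)
      got <- regional_map(as_grid(s), k)$scores
      expect_equal(got, oracle_regional(s, k$weights), tolerance = 1e-12)
    }
  }
})

test_that("the center-only kernel reproduces the cell grid exactly", {
  set.seed(13)
  s <- random_masked_grid(12, 14)
  rm_ <- regional_map(as_grid(s), make_kernel("center_only"))
  expect_identical(rm_$scores, s)
})

test_that("regional scores stay within their window's cell-score range", {
  set.seed(23)
  for (rep in 1:10) {
    s <- random_masked_grid(15, 14)
    k <- make_kernel(sample(c("default", "uniform", "gaussian"), 1))
    got <- regional_map(as_grid(s), k)$scores
    h <- 2L
    for (i in seq_len(nrow(s))) for (j in seq_len(ncol(s))) {
      if (is.na(got[i, j])) next
      win <- s[max(1, i - h):min(nrow(s), i + h),
               max(1, j - h):min(ncol(s), j + h)]
      expect_gte(got[i, j], min(win, na.rm = TRUE) - 1e-12)
      expect_lte(got[i, j], max(win, na.rm = TRUE) + 1e-12)
    }
  }
})

test_that("smoothing strength orders map variance: uniform <= default <= center-only", {
  set.seed(29)
  for (rep in 1:10) {
    s <- matrix(runif(20 * 14), 20, 14, dimnames = list(1:20, 1:14))
    v <- vapply(c("uniform", "default", "center_only"), function(p)
      stats::var(as.vector(regional_map(as_grid(s), make_kernel(p))$scores)),
      0.0)
    expect_lte(v[["uniform"]], v[["default"]] + 1e-12)
    expect_lte(v[["default"]], v[["center_only"]] + 1e-12)
  }
})

test_that("masked centers stay masked; masked neighbors are renormalized away", {
  s <- matrix(0.5, 6, 6, dimnames = list(1:6, 1:6))
  s[3, 3] <- NA
  s[3, 4] <- 1
  rm_ <- regional_map(as_grid(s), make_kernel("uniform"))
  expect_true(is.na(rm_$scores[3, 3]))
  # windows touching the hole average only over unmasked support
  expect_equal(rm_$scores[3, 4], (0.5 * 23 + 1) / 24)
})

test_that("cell ranking is deterministic with positional tie-breaks", {
  s <- matrix(0.4, 4, 3, dimnames = list(1:4, c(2, 5, 7)))
  rk <- rank_cells(as_grid(s))
  expect_equal(rk$repeat_index, rep(1:4, each = 3))
  expect_equal(rk$motif_position, rep(c(2L, 5L, 7L), 4))

  set.seed(31)
  s2 <- matrix(runif(12), 4, 3, dimnames = list(1:4, c(2, 5, 7)))
  up <- rank_cells(as_grid(s2), "divergent")
  down <- rank_cells(as_grid(s2), "conserved")
  expect_equal(up$score, rev(down$score))

  oversized <- as_grid(matrix(0.1, 2, 2, dimnames = list(1:2, 1:2)))
  expect_warning(regional_map(oversized, make_kernel()), "twice the grid")
})
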