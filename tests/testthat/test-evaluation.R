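test_that("decile assignment splits ranked cells into near-equal tenths", {
  s100 <- matrix(seq(1, 0.01, length.out = 100), 10, 10,
                 dimnames = list(1:10, 1:10))
  d <- decile_assign(as_grid(s100))
  expect_equal(as.integer(table(d)), rep(10L, 10))
  # highest scores sit in decile 1
  expect_equal(unique(d[s100 >= sort(s100, decreasing = TRUE)[10]]), 1L)

  set.seed(41)
  s101 <- matrix(runif(101), 101, 1, dimnames = list(1:101, 1))
  sizes <- as.integer(table(decile_assign(as_grid(s101))))
  expect_true(all(abs(sizes - 10.1) <= 1))
  expect_equal(sum(sizes), 101L)
  # matches the ceiling rule computed directly
  expect_equal(sort(sizes),
               sort(as.integer(table(ceiling(10 * (1:101) / 101)))))

  tiny <- matrix(runif(9), 3, 3, dimnames = list(1:3, 1:3))
  expect_error(decile_assign(as_grid(tiny)), "at least 10")
})

test_that("all-equal scores fill deciles in positional order", {
  s <- matrix(0.5, 10, 2, dimnames = list(1:10, c(1, 4)))
  d <- decile_assign(as_grid(s))
  # row-major positional ranks: cells of repeat 1 first
  expect_equal(d[1, ], c(`1` = 1L, `4` = 1L))
  expect_equal(d[10, ], c(`1` = 10L, `4` = 10L))
})

test_that("contact enrichment recovers constructed top-decile contacts", {
  set.seed(43)
  s <- matrix(runif(100), 10, 10, dimnames = list(1:10, 1:10))
  g <- as_grid(s)
  rk <- rank_cells(g)
  contacts <- utils::head(rk[, c("repeat_index", "motif_position")], 10)
  enr <- contact_enrichment(list(raw = g, weighted = g, regional = g),
                            contacts)
  expect_equal(unname(enr$top_decile_fraction), rep(1.0, 3))
  expect_equal(unname(enr$histogram[, 1]), rep(10L, 3))
  expect_equal(rowSums(enr$histogram), c(raw = 10, weighted = 10, regional = 10))
  # identical stage maps give identical histograms
  expect_equal(enr$histogram["raw", ], enr$histogram["regional", ])
  expect_error(contact_enrichment(list(g), contacts[0, ]), "empty")
})

test_that("random contacts spread roughly uniformly over deciles", {
  set.seed(47)
  s <- matrix(runif(200), 20, 10, dimnames = list(1:20, 1:10))
  g <- as_grid(s)
  cells <- expand.grid(repeat_index = 1:20, motif_position = 1:10)
  counts <- matrix(0, nrow = 500, ncol = 10)
  for (b in 1:500) {
    ct <- cells[sample(nrow(cells), 20), ]
    counts[b, ] <- contact_enrichment(list(g), ct)$histogram[1, ]
  }
  frac <- colMeans(counts) / 20
  expect_true(all(abs(frac - 0.1) < 0.03))
})

test_that("the enrichment histogram ignores added masked cells", {
  set.seed(53)
  s <- matrix(runif(100), 10, 10, dimnames = list(1:10, 1:10))
  contacts <- data.frame(repeat_index = c(2, 5, 9),
                         motif_position = c(3, 7, 1))
  base <- contact_enrichment(list(as_grid(s)), contacts)
  s2 <- rbind(s, matrix(NA_real_, 2, 10))
  rownames(s2) <- 1:12
  padded <- contact_enrichment(list(as_grid(s2)), contacts)
  expect_equal(base$histogram[1, ], padded$histogram[1, ])
})

test_that("the contact t-test separates distinct groups and is antisymmetric", {
  set.seed(59)
  s <- matrix(rnorm(100, 0, 0.01), 10, 10, dimnames = list(1:10, 1:10))
  contacts <- data.frame(repeat_index = c(1, 1, 2), motif_position = c(1, 2, 1))
  s[cbind(contacts$repeat_index, contacts$motif_position)] <- 1 + rnorm(3, 0, 0.01)
  tt <- contact_ttest(as_grid(s), contacts)
  expect_lt(tt$p_value, 1e-10)
  expect_equal(tt$n_contact, 3L)
  expect_equal(tt$n_other, 97L)
  expect_lte(tt$p_value, tt$p_two_sided)

  # swapping the group labels negates the statistic
  cells <- expand.grid(repeat_index = 1:10, motif_position = 1:10)
  key <- paste(contacts$repeat_index, contacts$motif_position)
  others <- cells[!paste(cells$repeat_index, cells$motif_position) %in% key, ]
  tt_sw <- contact_ttest(as_grid(s), others)
  expect_equal(tt_sw$t_statistic, -tt$t_statistic, tolerance = 1e-12)
})

test_that("t-test p-values are well calibrated under the null", {
  set.seed(61)
  p <- numeric(400)
  cells <- expand.grid(repeat_index = 1:10, motif_position = 1:10)
  for (b in seq_along(p)) {
    s <- matrix(rnorm(100), 10, 10, dimnames = list(1:10, 1:10))
    ct <- cells[sample(100, 8), ]
    p[b] <- contact_ttest(as_grid(s), ct)$p_value
  }
  expect_gt(mean(p), 0.42); expect_lt(mean(p), 0.58)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})

test_that("contact annotations round-trip through TSV", {
  contacts <- data.frame(repeat_index = c(3L, 4L, 9L),
                         motif_position = c(10L, 13L, 16L))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_contacts(contacts, path)
  expect_equal(read_contacts(path), contacts)
})
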