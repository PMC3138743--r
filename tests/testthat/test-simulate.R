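test_that("perfect repeat sequences are exact seeded tandem realizations", {
  m <- lrr_motif("lrr24")
  s <- perfect_repeat_sequence(m, 3, seed = 101)
  expect_equal(nchar(s), 72L)
  expect_identical(s, perfect_repeat_sequence(m, 3, seed = 101))
  expect_false(identical(s, perfect_repeat_sequence(m, 3, seed = 102)))
  # consensus positions carry their residues in every copy
  ch <- strsplit(s, "")[[1]]
  for (r in 0:2) {
    expect_equal(ch[r * 24 + 3], "L")
    expect_equal(ch[r * 24 + 17], "N")
    expect_equal(ch[r * 24 + 24], "P")
  }
  # detection closes the loop
  expect_length(detect_repeats(s, m)$repeats, 3L)
})

test_that("family generation is deterministic and respects its rates", {
  spec <- lrr_family_spec(n_repeats = 8, n_sequences = 3, seed = 111)
  f1 <- generate_family(spec)
  f2 <- generate_family(spec)
  expect_identical(f1$sequences, f2$sequences)

  # zero background mutation: all members identical, map flat at 1
  flat <- generate_family(lrr_family_spec(n_repeats = 6,
                                          background_mutation_rate = 0,
                                          seed = 121))
  expect_length(unique(flat$sequences), 1L)
  fit <- rcm(flat)
  expect_true(all(fit$weighted$scores == 1))
  expect_true(all(abs(fit$regional$scores - 1) < 1e-12))

  # saturating background: most non-patch variable cells change, patch and
  # consensus cells never do
  m <- lrr_motif("lrr24")
  sat <- generate_family(lrr_family_spec(n_repeats = 10, n_sequences = 2,
                                         background_mutation_rate = 1,
                                         seed = 131))
  a <- strsplit(sat$sequences[[1]], "")[[1]]
  b <- strsplit(sat$sequences[[2]], "")[[1]]
  cons <- unlist(lapply(0:9, function(r) r * 24 + m$consensus_columns))
  expect_equal(a[cons], b[cons])
  patch_pos <- (sat$patch$repeat_index - 1) * 24 + sat$patch$motif_position
  expect_equal(a[patch_pos], b[patch_pos])
  varpos <- setdiff(unlist(lapply(0:9, function(r) r * 24 + m$variable_columns)),
                    patch_pos)
  expect_gt(mean(a[varpos] != b[varpos]), 0.8)   # uniform resampling, 15 residues
})

test_that("the default patch is a 3x3 block of beta-region cells", {
  spec <- lrr_family_spec(n_repeats = 20, seed = 1)
  expect_equal(nrow(spec$patch), 9L)
  expect_length(unique(spec$patch$repeat_index), 3L)
  expect_true(all(diff(sort(unique(spec$patch$repeat_index))) == 1))
  expect_true(all(spec$patch$motif_position %in% spec$motif$beta_columns))
})

test_that("a patch mutating at the background rate shows no enrichment", {
  # null families: the "patch" is statistically indistinguishable from the
  # rest of the surface. The permutation null slides the 3x3 block over
  # every possible placement (placement permutation preserves the spatial
  # correlation of regional scores within a block).
  n_seeds <- 50
  calm <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    fam <- generate_family(lrr_family_spec(
      n_repeats = 20, seed = 5000 + k,
      background_mutation_rate = 0.5, patch_mutation_rate = 0.5))
    fit <- rcm(fam)
    s <- fit$regional$scores
    block_mean <- function(i, j) mean(s[i:(i + 2), j:(j + 2)])
    ri <- match(sort(unique(fam$patch$repeat_index)), rownames(s))[1]
    ci <- match(sort(unique(fam$patch$motif_position)), colnames(s))[1]
    obs <- block_mean(ri, ci)
    all_means <- as.vector(outer(seq_len(nrow(s) - 2), seq_len(ncol(s) - 2),
                                 Vectorize(block_mean)))
    pval <- mean(all_means >= obs)
    calm[k] <- pval > 0.05
  }
  expect_gte(sum(calm), ceiling(0.9 * n_seeds))
})

test_that("families are written as FASTA plus a contact-format patch TSV", {
  fam <- generate_family(lrr_family_spec(n_repeats = 5, seed = 141))
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_family(fam, dir)
  back <- read_sequences(paths[["fasta"]])
  expect_identical(back, fam$sequences)
  patch <- read_contacts(paths[["patch"]])
  expect_equal(patch$repeat_index, fam$patch$repeat_index)
  expect_equal(patch$motif_position, fam$patch$motif_position)
})
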