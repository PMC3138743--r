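test_that("identical sequences align gaplessly column for column", {
  s <- perfect_repeat_sequence(lrr_motif("lrr24"), 2, seed = 4)
  aln <- align_family(c(a = s, b = s))
  expect_false(any(grepl("-", aln$aligned, fixed = TRUE)))
  expect_equal(aln$aligned[["a"]], aln$aligned[["b"]])
})

test_that("pairwise alignments reach the exhaustive-search optimum", {
  mat <- rcm_matrix("blosum62")
  sf <- function(x, y) substitution_score(x, y, mat)
  cases <- list(c("LRRLRR", "LRR"),
                c("ACDEF", "ACF"),
                c("WLK", "WLKWLK"),
                c("LIVFM", "LIVFM"),
                c("KRE", "DQN"))
  for (cs in cases) {
    aln <- align_family(c(a = cs[1], b = cs[2]), matrix = mat)
    got <- score_pair_alignment(aln$aligned[["a"]], aln$aligned[["b"]],
                                sf, 10, 0.5)
    want <- oracle_align_score(cs[1], cs[2], sf, 10, 0.5)
    expect_equal(got, want, info = paste(cs, collapse = " vs "))
  }
})

test_that("alignment is invariant to input record order", {
  fam <- generate_family(lrr_family_spec(n_repeats = 4, n_sequences = 3,
                                         seed = 21))
  seqs <- fam$sequences
  ref <- align_family(seqs)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    aln <- align_family(seqs[p], reference = names(seqs)[1])
    expect_identical(aln$aligned[names(seqs)], ref$aligned[names(seqs)])
  }
})

test_that("aligned records always ungap back to their inputs", {
  fam <- generate_family(lrr_family_spec(n_repeats = 5, n_sequences = 4,
                                         seed = 31))
  aln <- align_family(fam$sequences)
  for (id in aln$ids)
    expect_equal(ungap(aln, id), unname(fam$sequences[[id]]))
})

test_that("pre-aligned input is validated, not re-aligned", {
  recs <- c(a = "LR-RL", b = "LRKRL")
  aln <- load_alignment(recs)
  expect_identical(aln$aligned, c(a = "LR-RL", b = "LRKRL"))
  expect_error(load_alignment(c(a = "LRRL", b = "LRKRL")), "unequal")
  expect_error(load_alignment(c(a = "LRRL")), "two sequences")
})

test_that("clustal and aligned-FASTA routes produce identical alignments", {
  fam <- generate_family(lrr_family_spec(n_repeats = 3, n_sequences = 3,
                                         seed = 41))
  aln <- align_family(fam$sequences)
  fa <- tempfile(fileext = ".fasta"); alnf <- tempfile(fileext = ".aln")
  on.exit(unlink(c(fa, alnf)))
  write_fasta(aln$aligned, fa)
  width <- 60L
  L <- nchar(aln$aligned[1])
  blocks <- unlist(lapply(seq(1L, L, by = width), function(st) {
    c(paste0(formatC(names(aln$aligned), width = 16, flag = "-"),
             substring(aln$aligned, st, min(st + width - 1L, L))), "")
  }))
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "", blocks),
             alnf)
  via_fasta <- read_alignment(fa)
  via_clustal <- read_alignment(alnf)
  expect_identical(via_fasta$aligned[via_fasta$ids],
                   via_clustal$aligned[via_fasta$ids])
})

test_that("grid cells map to the alignment columns of their residues", {
  m <- lrr_motif("lrr24")
  s <- perfect_repeat_sequence(m, 3, seed = 51)
  ann <- detect_repeats(s, m)

  # gapless alignment: column = 0-based sequence index + 1
  aln <- load_alignment(c(ref = s, hom = s))
  cm <- map_cells_to_columns(ann, aln)
  vc <- m$variable_columns
  for (r in 1:3)
    expect_equal(unname(cm[r, ]), (r - 1L) * 24L + vc)

  # a gap inserted into the reference shifts downstream columns by one
  gap_at <- 30L
  gapped <- paste0(substr(s, 1, gap_at - 1), "-",
                   substr(s, gap_at, nchar(s)))
  filler <- paste(rep("A", nchar(gapped)), collapse = "")
  aln2 <- load_alignment(c(ref = gapped, hom = filler))
  cm2 <- map_cells_to_columns(ann, aln2)
  expect_equal(cm2[cm <= gap_at - 1L], cm[cm <= gap_at - 1L])
  expect_equal(cm2[cm >= gap_at], cm[cm >= gap_at] + 1L)

  # unmasked cells map injectively
  expect_false(any(duplicated(cm2[!is.na(cm2)])))

  # hole cells stay masked
  ann2 <- apply_curation(ann, data.frame(seq_id = "query", repeat_index = 2L,
                                         motif_position = 1L,
                                         seq_index = NA_integer_))
  cm3 <- map_cells_to_columns(ann2, aln)
  expect_true(is.na(cm3[2, 1]))
  expect_equal(sum(is.na(cm3)), 1L)
})
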