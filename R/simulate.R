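# Synthetic LRR families with known ground truth: a designated conserved
# patch on an otherwise randomized variable surface. The generator models
# the star topology that unweighted pairwise scoring implicitly assumes;
# it makes no indels, so families align gaplessly.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  code
}

.nonconsensus_residues <- function(motif) {
  used <- unique(unlist(lapply(motif$tokens, `[[`, "residues")))
  setdiff(.AA20, used)
}

#' One perfect tandem realization of a consensus motif
#'
#' Fixed tokens emit their residue, alternative tokens pick uniformly
#' among their alternatives, wildcards pick uniformly from the residues
#' not used by the consensus (maximizing contrast between consensus and
#' variable positions).
#'
#' @param motif An [lrr_motif()].
#' @param n_repeats Number of tandem copies.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Amino-acid string of length `n_repeats * motif$length`.
#' @export
perfect_repeat_sequence <- function(motif = lrr_motif(), n_repeats,
                                    seed = NULL) {
  if (!inherits(motif, "lrr_motif")) motif <- lrr_motif(motif)
  stopifnot(n_repeats >= 1L)
  pool <- .nonconsensus_residues(motif)
  .with_seed(seed, {
    paste(vapply(seq_len(n_repeats), function(r) {
      paste(vapply(motif$tokens, function(tk) switch(tk$type,
        fixed = tk$residues,
        alt = sample(tk$residues, 1L),
        wild = sample(pool, 1L)), ""), collapse = "")
    }, ""), collapse = "")
  })
}

#' Specification of a synthetic LRR family
#'
#' @param n_repeats Repeats in the reference sequence; default 20.
#' @param n_sequences Family size (>= 2); default 4.
#' @param motif An [lrr_motif()]; default the generic 24-mer consensus.
#' @param background_mutation_rate Per-cell probability that a non-patch
#'   variable cell is resampled in each non-reference member; default 0.5.
#' @param patch data.frame (`repeat_index`, `motif_position`) of conserved
#'   cells, or `NULL` for the default 3x3 block centered on the grid over
#'   the middle three beta-region columns (where ligand contacts sit in
#'   solved LRR structures).
#' @param patch_mutation_rate Per-cell mutation probability inside the
#'   patch; default 0 (perfectly conserved).
#' @param seed Integer seed driving the whole family.
#' @param residue_freqs Optional named probability vector over residues for
#'   wildcard resampling (default uniform over non-consensus residues).
#' @return List of class `"lrr_family_spec"`.
#' @export
lrr_family_spec <- function(n_repeats = 20L, n_sequences = 4L,
                            motif = lrr_motif(),
                            background_mutation_rate = 0.5,
                            patch = NULL, patch_mutation_rate = 0,
                            seed = 1L, residue_freqs = NULL) {
  if (!inherits(motif, "lrr_motif")) motif <- lrr_motif(motif)
  stopifnot(n_repeats >= 1L, n_sequences >= 2L,
            background_mutation_rate >= 0, background_mutation_rate <= 1,
            patch_mutation_rate >= 0, patch_mutation_rate <= 1)
  if (is.null(patch)) {
    rows <- if (n_repeats >= 3L) {
      start <- min(max(1L, floor(n_repeats / 2) - 1L), n_repeats - 2L)
      start:(start + 2L)
    } else seq_len(n_repeats)
    beta <- sort(motif$beta_columns)
    cols <- if (length(beta) >= 3L) {
      c0 <- (length(beta) + 1L) %/% 2L
      beta[(c0 - 1L):(c0 + 1L)]
    } else motif$variable_columns[seq_len(min(3L, length(motif$variable_columns)))]
    patch <- expand.grid(repeat_index = rows, motif_position = cols)
  }
  stopifnot(all(patch$repeat_index >= 1L), all(patch$repeat_index <= n_repeats),
            all(patch$motif_position %in% motif$variable_columns))
  structure(list(n_repeats = as.integer(n_repeats),
                 n_sequences = as.integer(n_sequences), motif = motif,
                 background_mutation_rate = background_mutation_rate,
                 patch = patch[, c("repeat_index", "motif_position")],
                 patch_mutation_rate = patch_mutation_rate,
                 seed = as.integer(seed), residue_freqs = residue_freqs),
            class = "lrr_family_spec")
}

#' Generate a synthetic LRR family with a known conserved patch
#'
#' The reference is a perfect tandem realization of the motif; every other
#' member copies it and independently resamples each variable cell with
#' the background mutation rate (patch cells with the patch rate).
#' Consensus cells are never touched, so repeat detection stays exact and
#' the family aligns without gaps.
#'
#' @param spec An [lrr_family_spec()].
#' @return Object of class `"lrr_family"`: list with `sequences` (named
#'   character, reference first), `patch` (ground-truth contact cells),
#'   `spec`.
#' @export
generate_family <- function(spec = lrr_family_spec()) {
  stopifnot(inherits(spec, "lrr_family_spec"))
  motif <- spec$motif
  m <- motif$length
  pool <- .nonconsensus_residues(motif)
  probs <- NULL
  if (!is.null(spec$residue_freqs)) {
    pool <- names(spec$residue_freqs)
    probs <- spec$residue_freqs / sum(spec$residue_freqs)
  }
  patch_key <- paste(spec$patch$repeat_index, spec$patch$motif_position)
  .with_seed(spec$seed, {
    ref <- perfect_repeat_sequence(motif, spec$n_repeats, seed = NULL)
    seqs <- character(spec$n_sequences)
    seqs[1] <- ref
    cells <- expand.grid(r = seq_len(spec$n_repeats),
                         p = motif$variable_columns)
    rate <- ifelse(paste(cells$r, cells$p) %in% patch_key,
                   spec$patch_mutation_rate, spec$background_mutation_rate)
    pos <- (cells$r - 1L) * m + cells$p      # 1-based position in sequence
    for (k in 2:spec$n_sequences) {
      ch <- .split1(ref)
      hit <- stats::runif(nrow(cells)) < rate
      if (any(hit))
        ch[pos[hit]] <- sample(pool, sum(hit), replace = TRUE, prob = probs)
      seqs[k] <- paste(ch, collapse = "")
    }
    names(seqs) <- sprintf("syn%02d", seq_len(spec$n_sequences))
    structure(list(sequences = seqs, patch = spec$patch, spec = spec),
              class = "lrr_family")
  })
}

#' @export
print.lrr_family <- function(x, ...) {
  cat("Synthetic LRR family: ", length(x$sequences), " sequences, ",
      x$spec$n_repeats, " repeats, background mutation rate ",
      x$spec$background_mutation_rate, ", patch of ", nrow(x$patch),
      " cells (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic family to disk
#'
#' Emits standard FASTA plus the ground-truth patch as a contact TSV
#' directly consumable by the evaluation functions.
#'
#' @param family An `"lrr_family"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "lrr_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "family.fasta")
  write_fasta(family$sequences, fa)
  tsv <- file.path(dir, "patch.tsv")
  write_contacts(family$patch, tsv)
  invisible(c(fasta = fa, patch = tsv))
}
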