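# Family alignment: an internal progressive aligner (pairwise Gotoh on
# profile score matrices, neighbor-joining guide tree) plus a validated
# pass-through for pre-aligned input, and the mapping from reference grid
# cells to alignment columns.

.split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# residue-frequency profile (20 x L) of a set of aligned rows; gaps
# contribute nothing, X spreads uniformly
.alignment_profile <- function(aligned) {
  L <- nchar(aligned[1])
  prof <- matrix(0, nrow = 20L, ncol = L, dimnames = list(.AA20, NULL))
  for (s in aligned) {
    ch <- .split1(s)
    known <- ch %in% .AA20
    idx <- match(ch[known], .AA20)
    cols <- which(known)
    for (k in seq_along(cols)) prof[idx[k], cols[k]] <- prof[idx[k], cols[k]] + 1
    xcols <- which(ch == "X")
    if (length(xcols)) prof[, xcols] <- prof[, xcols] + 1 / 20
  }
  prof / length(aligned)
}

# merge two sub-alignments with the Gotoh DP; returns list(aligned, score)
.merge_alignments <- function(alnA, alnB, S20, gap_open, gap_ext) {
  pa <- .alignment_profile(alnA)
  pb <- .alignment_profile(alnB)
  C <- crossprod(pa, S20 %*% pb)           # expected column-pair scores
  hit <- .gotoh_align(C, gap_open, gap_ext)
  expand <- function(rows, idx) {
    vapply(rows, function(s) {
      ch <- .split1(s)
      paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    }, "")
  }
  out <- c(expand(alnA, hit$a_idx), expand(alnB, hit$b_idx))
  list(aligned = out, score = hit$score)
}

#' Progressively align a family of LRR domain sequences
#'
#' Pairwise global alignment with affine gap penalties (default gap open
#' 10, extend 0.5) provides identity distances; a neighbor-joining guide
#' tree orders profile merges. The procedure is deterministic: records are
#' canonically ordered lexicographically by id before any computation, so
#' the result is invariant to input order.
#'
#' @param sequences Named character vector of >= 2 unaligned amino-acid
#'   sequences (unique names).
#' @param matrix Substitution matrix id or [rcm_matrix()] object.
#' @param gap_open,gap_ext Affine gap penalties (positive numbers).
#' @param reference Id of the sequence whose repeats define the grid;
#'   default the first input record.
#' @return Object of class `"lrr_alignment"`: list with `ids`, `aligned`
#'   (named, equal-length gapped sequences in input order) and
#'   `reference_id`.
#' @export
align_family <- function(sequences, matrix = rcm_matrix(),
                         gap_open = 10, gap_ext = 0.5,
                         reference = NULL) {
  if (!inherits(matrix, "rcm_submat")) matrix <- rcm_matrix(matrix)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("sequences must carry unique non-empty names")
  if (length(sequences) < 2L)
    stop("at least two homologous sequences are required")
  sequences <- toupper(sequences)
  for (id in ids) {
    ch <- .split1(sequences[[id]])
    if (length(ch) < 1L) stop("sequence '", id, "' is empty")
    if (!all(ch %in% c(.AA20, "X")))
      stop("sequence '", id, "' contains non-residue characters")
  }
  if (is.null(reference)) reference <- ids[1]
  if (!reference %in% ids) stop("reference id '", reference, "' not among inputs")

  S20 <- matrix$entries[.AA20, .AA20]
  ord <- order(ids, method = "radix")       # canonical, locale-free
  cids <- ids[ord]
  cseqs <- sequences[ord]
  n <- length(cids)

  if (n == 2L) {
    merged <- .merge_alignments(cseqs[1], cseqs[2], S20, gap_open, gap_ext)$aligned
    names(merged) <- cids
  } else {
    # pairwise identity distances from pairwise Gotoh alignments
    D <- matrix(0, n, n, dimnames = list(cids, cids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      mr <- .merge_alignments(cseqs[i], cseqs[j], S20, gap_open, gap_ext)
      a <- .split1(mr$aligned[1]); b <- .split1(mr$aligned[2])
      D[i, j] <- D[j, i] <- 1 - sum(a == b & a != "-") / length(a)
    }
    tree <- ape::nj(stats::as.dist(D))
    tree <- ape::root(tree, outgroup = cids[1], resolve.root = TRUE)
    merged <- .align_tree_node(tree, length(tree$tip.label) + 1L, cseqs,
                               S20, gap_open, gap_ext)
  }
  aligned <- merged[ids]                    # back to input order
  for (id in ids) {
    if (gsub("-", "", aligned[[id]], fixed = TRUE) != sequences[[id]])
      stop("internal error: alignment does not conserve residues of '", id, "'")
  }
  structure(list(ids = ids, aligned = aligned, reference_id = reference,
                 aligner = list(matrix_id = matrix$matrix_id,
                                gap_open = gap_open, gap_ext = gap_ext)),
            class = "lrr_alignment")
}

# post-order merge of the rooted guide tree; children visited in order of
# their lexicographically smallest descendant leaf
.align_tree_node <- function(tree, node, seqs, S20, gap_open, gap_ext) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    out <- seqs[tree$tip.label[node]]
    return(out)
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  minleaf <- vapply(children, function(ch) min(.leaf_labels(tree, ch)), "")
  children <- children[order(minleaf, method = "radix")]
  acc <- NULL
  for (ch in children) {
    sub <- .align_tree_node(tree, ch, seqs, S20, gap_open, gap_ext)
    acc <- if (is.null(acc)) sub
           else .merge_alignments(acc, sub, S20, gap_open, gap_ext)$aligned
  }
  acc
}

.leaf_labels <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  unlist(lapply(tree$edge[tree$edge[, 1] == node, 2],
                function(ch) .leaf_labels(tree, ch)))
}

#' Ingest a pre-computed multiple alignment
#'
#' Validated pass-through for externally aligned input (e.g. a ClustalW
#' alignment): all records must have equal gapped length.
#'
#' @param aligned Named character vector of >= 2 aligned sequences
#'   (residues plus `-`).
#' @param reference Reference id; default first record.
#' @return An `"lrr_alignment"` object.
#' @export
load_alignment <- function(aligned, reference = NULL) {
  ids <- names(aligned)
  if (is.null(ids) || anyDuplicated(ids)) stop("aligned records need unique names")
  if (length(aligned) < 2L) stop("at least two sequences are required")
  aligned <- toupper(aligned)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L)
    stop("aligned records have unequal lengths: ",
         paste(sprintf("%s (%d)", ids[lens != stats::median(lens)],
                       lens[lens != stats::median(lens)]), collapse = ", "))
  for (id in ids) {
    ch <- .split1(aligned[[id]])
    if (!all(ch %in% c(.AA20, "X", "-")))
      stop("record '", id, "' contains non-residue characters")
  }
  if (is.null(reference)) reference <- ids[1]
  if (!reference %in% ids) stop("reference id '", reference, "' not among records")
  structure(list(ids = ids, aligned = aligned, reference_id = reference,
                 aligner = list(matrix_id = "external")),
            class = "lrr_alignment")
}

#' @export
print.lrr_alignment <- function(x, ...) {
  cat("LRR family alignment: ", length(x$ids), " sequences, ",
      nchar(x$aligned[1]), " columns (reference: ", x$reference_id, ")\n",
      sep = "")
  invisible(x)
}

#' Ungap an aligned record
#' @param alignment An `"lrr_alignment"`.
#' @param id Record id.
#' @return The original unaligned sequence.
#' @export
ungap <- function(alignment, id) {
  stopifnot(inherits(alignment, "lrr_alignment"))
  gsub("-", "", alignment$aligned[[id]], fixed = TRUE)
}

#' Map reference grid cells to alignment columns
#'
#' Each (repeat, variable position) cell of the reference repeat model is
#' converted from its 0-based sequence index to the alignment column that
#' holds that reference residue, so every homolog contributes one symbol
#' (residue or gap) per cell. Hole cells stay masked (`NA`).
#'
#' @param annotation `"lrr_repeats"` for the reference sequence.
#' @param alignment `"lrr_alignment"` containing the reference.
#' @return Integer matrix (repeats x variable columns) of 1-based alignment
#'   columns, `NA` = masked; `dimnames` give repeat numbers and motif
#'   positions.
#' @export
map_cells_to_columns <- function(annotation, alignment) {
  stopifnot(inherits(annotation, "lrr_repeats"),
            inherits(alignment, "lrr_alignment"))
  ref <- alignment$aligned[[alignment$reference_id]]
  refseq <- gsub("-", "", ref, fixed = TRUE)
  if (refseq != annotation$sequence)
    stop("annotation sequence does not match the ungapped reference record")
  col_of_res <- which(.split1(ref) != "-")   # residue k -> alignment column
  vc <- annotation$motif$variable_columns
  nr <- length(annotation$repeats)
  out <- matrix(NA_integer_, nrow = nr, ncol = length(vc),
                dimnames = list(seq_len(nr), vc))
  for (r in seq_len(nr)) {
    idx <- annotation$repeats[[r]][vc]       # 0-based or NA
    ok <- !is.na(idx)
    if (any(idx[ok] + 1L > length(col_of_res)))
      stop("annotation index beyond reference length in repeat ", r)
    out[r, ok] <- col_of_res[idx[ok] + 1L]
  }
  out
}
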