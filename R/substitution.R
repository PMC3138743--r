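# Substitution matrices and pairwise conservation scores.
#
# BLOSUM62 is taken from Biostrings. BLOSUM65 (the matrix used for the
# original validation maps) is not shipped by Biostrings, so the published
# NCBI matblas table (1/2-bit units, >=65% clustering) is transcribed here.

.BLOSUM65_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                        "B", "Z", "X")

.BLOSUM65 <- local({
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-2,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1,-1,
    -1, 6, 0,-2,-4, 1, 0,-2, 0,-3,-2, 2,-2,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,
    -2, 0, 6, 1,-3, 0, 0,-1, 1,-3,-4, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,
    -2,-2, 1, 6,-4, 0, 2,-1,-1,-3,-4,-1,-3,-4,-2, 0,-1,-5,-3,-3, 4, 1,-1,
     0,-4,-3,-4, 9,-3,-4,-3,-3,-1,-1,-3,-2,-2,-3,-1,-1,-2,-2,-1,-3,-4,-2,
    -1, 1, 0, 0,-3, 6, 2,-2, 1,-3,-2, 1, 0,-3,-1, 0,-1,-2,-2,-2, 0, 3,-1,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-3, 1, 4,-1,
     0,-2,-1,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-3,-3,-3,-1,-2,-2,
    -2, 0, 1,-1,-3, 1, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-2,-1, 3,-3,-3,-1,
    -2,-2,-4,-4,-1,-2,-3,-4,-3, 2, 4,-3, 2, 0,-3,-3,-1,-2,-1, 1,-4,-3,-1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-3, 5,-2,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,
    -1,-2,-2,-3,-2, 0,-2,-3,-2, 1, 2,-2, 6, 0,-3,-2,-1,-2,-1, 1,-3,-2,-1,
    -2,-3,-3,-4,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-2,
    -1,-2,-2,-2,-3,-1,-1,-2,-2,-3,-3,-1,-3,-4, 8,-1,-1,-4,-3,-2,-2,-1,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-3, 0,-2,-2,-1, 4, 1,-3,-2,-2, 0, 0,-1,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-3,-2, 0,-1,-1,-1,
    -3,-3,-4,-5,-2,-2,-3,-3,-2,-2,-2,-3,-2, 1,-4,-3,-3,10, 2,-3,-4,-3,-2,
    -2,-2,-2,-3,-2,-2,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,
     0,-3,-3,-3,-1,-2,-3,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,
    -2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,
    -1, 0, 0, 1,-4, 3, 4,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,
    -1,-1,-1,-1,-2,-1,-1,-2,-1,-1,-1,-1,-1,-2,-2,-1,-1,-2,-1,-1,-1,-1,-1)
  m <- matrix(v, nrow = 23, byrow = TRUE,
              dimnames = list(.BLOSUM65_ALPHABET, .BLOSUM65_ALPHABET))
  storage.mode(m) <- "integer"
  m
})

#' Load a substitution matrix for conservation scoring
#'
#' @param matrix_id `"blosum62"` (default; from Biostrings) or `"blosum65"`
#'   (the matrix named for the original validation maps), or a symmetric
#'   numeric matrix with residue-letter dimnames to use as-is.
#' @return An object of class `"rcm_submat"`: list with `matrix_id`,
#'   `entries` (integer matrix over the residue alphabet incl. B/Z/X),
#'   and `global_min` (minimum entry over the 20 standard residues, the
#'   floor used by the normalized pairwise score).
#' @examples
#' b62 <- rcm_matrix("blosum62")
#' b62$global_min  # -4
#' @export
rcm_matrix <- function(matrix_id = "blosum62") {
  if (is.matrix(matrix_id)) {
    m <- matrix_id
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      stop("a custom matrix needs identical row and column residue names")
    id <- "custom"
  } else {
    id <- tolower(matrix_id)
    m <- switch(id,
      blosum62 = {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        keep <- c(.AA20, "B", "Z", "X")
        e$BLOSUM62[keep, keep]
      },
      blosum65 = .BLOSUM65,
      stop("unknown matrix id '", matrix_id, "' (use blosum62 or blosum65)"))
  }
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric")
  core <- intersect(.AA20, rownames(m))
  diag_ok <- all(vapply(core, function(a)
    m[a, a] >= max(m[a, setdiff(core, a)]), TRUE))
  if (!diag_ok)
    warning("matrix is not diagonal-dominant; identity may not score maximal")
  structure(list(matrix_id = id,
                 entries = m,
                 global_min = min(m[core, core]),
                 diagonal_dominant = diag_ok),
            class = "rcm_submat")
}

.lookup_residue <- function(a, matrix) {
  if (a %in% rownames(matrix$entries)) return(a)
  if ("X" %in% rownames(matrix$entries)) return("X")
  stop("residue '", a, "' not in substitution matrix alphabet")
}

#' Raw substitution score for a residue pair
#'
#' Symmetric lookup in the run's substitution matrix. Residues absent from
#' the matrix alphabet are scored as `X` when the matrix defines it.
#'
#' @param a,b Single residue letters.
#' @param matrix An [rcm_matrix()].
#' @return Integer matrix entry.
#' @export
substitution_score <- function(a, b, matrix = rcm_matrix()) {
  stopifnot(inherits(matrix, "rcm_submat"))
  matrix$entries[.lookup_residue(toupper(a), matrix),
                 .lookup_residue(toupper(b), matrix)]
}

#' Normalized ("weighted") pairwise score in \[0, 1\]
#'
#' `w(a,b) = clip((S(a,b) - S_min) / (min(S(a,a), S(b,b)) - S_min), 0, 1)`
#' where `S_min` is the matrix minimum over the 20 standard residues.
#' Identity maps to 1, the most dissimilar substitution to 0. Any pair
#' involving a gap scores 0: an indel at an exposed position is treated as
#' evidence of non-conservation.
#'
#' @inheritParams substitution_score
#' @return Numeric in \[0, 1\].
#' @examples
#' normalized_pair_score("L", "I")  # (2 + 4) / (4 + 4) = 0.75 with BLOSUM62
#' @export
normalized_pair_score <- function(a, b, matrix = rcm_matrix()) {
  stopifnot(inherits(matrix, "rcm_submat"))
  if (a == "-" || b == "-") return(0)
  s <- substitution_score(a, b, matrix)
  self_min <- min(substitution_score(a, a, matrix),
                  substitution_score(b, b, matrix))
  denom <- self_min - matrix$global_min
  if (denom <= 0) return(0)
  min(max((s - matrix$global_min) / denom, 0), 1)
}
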