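#' LRR consensus motif presets
#'
#' Two repeat consensus models ship with the package: `"lrr24"`, the generic
#' 24-residue LRR consensus `xxLxxLxxLxxLxLxxNxLxGxIP`, and `"plant"`, the
#' plant extracellular LRR subfamily consensus `xxLxLxxNxLt/sGxIPxxLxxLxxL`
#' (a rotation of the same repeat architecture, with a T-or-S alternative
#' position). Lowercase `x` marks a variable (solvent-exposed) position;
#' every other letter is a buried consensus residue.
#' @keywords internal
.motif_presets <- c(
  lrr24 = "xxLxxLxxLxxLxLxxNxLxGxIP",
  plant = "xxLxLxxNxLt/sGxIPxxLxxLxxL"
)

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse an LRR consensus motif
#'
#' Tokenizes a consensus motif string into fixed-residue, alternative
#' (`a/b`), and wildcard (`x`) position tokens, and locates the
#' beta-strand/beta-turn sub-region: the motif is treated cyclically (repeat
#' phase is arbitrary) and scanned for the nine-position pattern
#' `L-x-x-L-x-L-x-x-N`; the five wildcard positions inside the match form
#' the beta region, the concave ligand-binding face in most solved LRR
#' structures.
#'
#' @param motif Motif text, or a preset name (`"lrr24"` or `"plant"`).
#' @return An object of class `"lrr_motif"`: a list with elements
#'   `text`, `tokens` (list of per-position tokens, each with `type`
#'   one of `"fixed"`, `"alt"`, `"wild"` and a `residues` character vector),
#'   `length`, `variable_columns` (1-based wildcard positions),
#'   `consensus_columns`, and `beta_columns` (five wildcard positions, in
#'   beta-pattern order; empty with a warning when no match exists).
#' @examples
#' m <- lrr_motif("lrr24")
#' m$length            # 24
#' m$beta_columns      # 10 11 13 15 16
#' @export
lrr_motif <- function(motif = "lrr24") {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif) || !nzchar(motif))
    stop("motif text must be a non-empty character scalar")
  if (motif %in% names(.motif_presets)) motif <- .motif_presets[[motif]]

  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (i + 2L <= length(chars) && chars[i + 1L] == "/") {
      a <- toupper(ch); b <- toupper(chars[i + 2L])
      if (!all(c(a, b) %in% .AA20))
        stop("illegal alternative group '", ch, "/", chars[i + 2L], "' in motif")
      tokens[[length(tokens) + 1L]] <- list(type = "alt", residues = c(a, b))
      i <- i + 3L
    } else if (ch %in% c("x", "X")) {
      tokens[[length(tokens) + 1L]] <- list(type = "wild", residues = character(0))
      i <- i + 1L
    } else if (toupper(ch) %in% .AA20) {
      tokens[[length(tokens) + 1L]] <- list(type = "fixed", residues = toupper(ch))
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' in motif")
    }
  }

  n <- length(tokens)
  types <- vapply(tokens, `[[`, "", "type")
  if (n < 6L) stop("motif must have at least 6 positions")
  if (!any(types == "wild")) stop("motif must contain at least one wildcard ('x') position")

  out <- structure(list(
    text = motif,
    tokens = tokens,
    length = n,
    variable_columns = which(types == "wild"),
    consensus_columns = which(types != "wild"),
    beta_columns = .find_beta_columns(tokens)
  ), class = "lrr_motif")
  out
}

# Cyclic scan for L-x-x-L-x-L-x-x-N; returns the wildcard positions of the
# first match in pattern order (1-based motif positions).
.find_beta_columns <- function(tokens) {
  pat <- c("L", "x", "x", "L", "x", "L", "x", "x", "N")
  n <- length(tokens)
  if (n < length(pat)) {
    warning("motif shorter than the beta pattern; beta region left empty")
    return(integer(0))
  }
  for (start in seq_len(n)) {
    pos <- ((start - 1L + seq_along(pat) - 1L) %% n) + 1L
    ok <- TRUE
    for (k in seq_along(pat)) {
      tk <- tokens[[pos[k]]]
      if (pat[k] == "x") {
        if (tk$type != "wild") { ok <- FALSE; break }
      } else {
        if (tk$type != "fixed" || tk$residues != pat[k]) { ok <- FALSE; break }
      }
    }
    if (ok) return(pos[pat == "x"])
  }
  warning("beta pattern L-x-x-L-x-L-x-x-N not found in motif; beta region left empty")
  integer(0)
}

#' Partition motif positions into variable and consensus classes
#'
#' The structural premise of conservation mapping: consensus residues are
#' buried in the solenoid core, wildcard positions are solvent-exposed and
#' form the cells of the surface grid.
#'
#' @param motif An [lrr_motif()].
#' @return A list with `variable_columns`, `consensus_columns` and
#'   `beta_columns` (all 1-based motif positions).
#' @export
classify_positions <- function(motif) {
  stopifnot(inherits(motif, "lrr_motif"))
  list(variable_columns = motif$variable_columns,
       consensus_columns = motif$consensus_columns,
       beta_columns = motif$beta_columns)
}

#' @export
print.lrr_motif <- function(x, ...) {
  cat("LRR consensus motif: ", x$text, "\n", sep = "")
  cat("  positions: ", x$length,
      "  (", length(x$variable_columns), " variable, ",
      length(x$consensus_columns), " consensus)\n", sep = "")
  if (length(x$beta_columns))
    cat("  beta-strand/beta-turn columns: ",
        paste(x$beta_columns, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Grid cell labels of the form "repeat.beta-position"
#'
#' Cells on the concave face are conventionally labelled `"N.M"`: `M`-th
#' variable position of the `L-x-x-L-x-L-x-x-N` segment in the `N`-th
#' repeat (e.g. `"2.3"` is the third x position in the second repeat).
#'
#' @param repeat_index 1-based repeat number(s).
#' @param beta_position 1-based position within the beta region, in 1..5.
#' @return Character label(s).
#' @seealso [parse_cell_label()]
#' @export
cell_label <- function(repeat_index, beta_position) {
  repeat_index <- as.integer(repeat_index)
  beta_position <- as.integer(beta_position)
  if (any(is.na(repeat_index)) || any(repeat_index < 1L))
    stop("repeat_index must be a positive integer")
  if (any(is.na(beta_position)) || any(beta_position < 1L) || any(beta_position > 5L))
    stop("beta_position must be in 1..5")
  paste0(repeat_index, ".", beta_position)
}

#' Parse a "repeat.beta-position" cell label
#'
#' @param label Label(s) such as `"2.3"`.
#' @return A data.frame with integer columns `repeat_index`, `beta_position`.
#' @export
parse_cell_label <- function(label) {
  parts <- regmatches(label, regexec("^([0-9]+)\\.([1-5])$", label))
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) stop("malformed cell label: ", paste(label[bad], collapse = ", "))
  data.frame(
    repeat_index = as.integer(vapply(parts, `[`, "", 2L)),
    beta_position = as.integer(vapply(parts, `[`, "", 3L))
  )
}
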