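# Repeat detection: greedy left-to-right scan of a protein sequence against
# a consensus motif, allowing a small per-repeat indel budget, plus
# hand-curation of the resulting repeat model.

.RELAXED_L <- c("L", "I", "V", "F", "M")

# Per-token residue matcher over the whole sequence; rows = motif tokens,
# cols = sequence positions. Wildcards match everything but never count.
.token_match_matrix <- function(chars, motif, relaxed_leucine) {
  m <- motif$length
  out <- matrix(FALSE, nrow = m, ncol = length(chars))
  for (i in seq_len(m)) {
    tk <- motif$tokens[[i]]
    out[i, ] <- switch(tk$type,
      wild = TRUE,
      alt = chars %in% tk$residues,
      fixed = if (relaxed_leucine && tk$residues == "L")
        chars %in% .RELAXED_L else chars == tk$residues)
  }
  out
}

# Best gapped placement of the motif starting at sequence offset `pos`
# (1-based): maximize matched consensus tokens with at most `budget` total
# insertions+deletions; ties broken toward fewer indels, then fewer
# insertions. Returns matches, consumed length and the motif-position ->
# 0-based sequence-index mapping (NA = hole).
.match_motif_at <- function(pos, n, matchmat, consensus, m, budget) {
  NEG <- -1e9
  score <- array(NEG, dim = c(m + 1L, budget + 1L, budget + 1L))
  ptr <- array(0L, dim = c(m + 1L, budget + 1L, budget + 1L))
  score[1, 1, 1] <- 0
  for (i in 0:m) for (ins in 0:budget) for (del in 0:budget) {
    s <- score[i + 1L, ins + 1L, del + 1L]
    if (s <= NEG) next
    j <- pos - 1L + i - del + ins            # residues consumed so far
    if (i < m) {
      if (j < n) {                           # align token i+1 to residue j+1
        gain <- if (consensus[i + 1L] && matchmat[i + 1L, j + 1L]) 1 else 0
        if (s + gain > score[i + 2L, ins + 1L, del + 1L]) {
          score[i + 2L, ins + 1L, del + 1L] <- s + gain
          ptr[i + 2L, ins + 1L, del + 1L] <- 1L
        }
      }
      if (del < budget && s > score[i + 2L, ins + 1L, del + 2L]) {
        score[i + 2L, ins + 1L, del + 2L] <- s    # token i+1 -> hole
        ptr[i + 2L, ins + 1L, del + 2L] <- 2L
      }
    }
    if (ins < budget && j < n && s > score[i + 1L, ins + 2L, del + 1L]) {
      score[i + 1L, ins + 2L, del + 1L] <- s      # unassigned inserted residue
      ptr[i + 1L, ins + 2L, del + 1L] <- 3L
    }
  }
  best <- c(NEG, Inf, Inf); bi <- NULL
  for (ins in 0:budget) for (del in 0:budget) {
    s <- score[m + 1L, ins + 1L, del + 1L]
    if (s <= NEG) next
    key <- c(s, -(ins + del), -ins)
    if (is.null(bi) || key[1] > best[1] ||
        (key[1] == best[1] && (key[2] > best[2] ||
         (key[2] == best[2] && key[3] > best[3])))) {
      best <- key; bi <- c(ins, del)
    }
  }
  if (is.null(bi)) return(NULL)
  mapping <- rep(NA_integer_, m)
  i <- m; ins <- bi[1]; del <- bi[2]
  while (i > 0L || ins > 0L || del > 0L) {
    p <- ptr[i + 1L, ins + 1L, del + 1L]
    if (p == 1L) {
      mapping[i] <- pos - 1L + i - del + ins - 1L  # 0-based
      i <- i - 1L
    } else if (p == 2L) {
      i <- i - 1L; del <- del - 1L
    } else {
      ins <- ins - 1L
    }
  }
  list(matches = best[1], indels = sum(bi),
       consumed = m - bi[2] + bi[1], mapping = mapping)
}

#' Detect LRR repeats in a protein sequence
#'
#' Greedy left-to-right scan: at each candidate offset the motif is placed
#' with up to `indel_budget` insertions/deletions and the placement
#' maximizing matched consensus tokens is kept; a window is accepted as a
#' repeat when at least `min_match_fraction` of the motif's fixed and
#' alternative tokens match. Under the relaxed-leucine option (standard LRR
#' practice) a consensus `L` matches any of L, I, V, F, M. Accepted repeats
#' are non-overlapping and ordered N-terminus to C-terminus.
#'
#' @param sequence Amino-acid string (20-letter alphabet plus `X`).
#' @param motif An [lrr_motif()] or preset name / motif text.
#' @param min_match_fraction Fraction of consensus tokens that must match
#'   for acceptance; default 0.6.
#' @param indel_budget Maximum insertions + deletions per repeat; default 2.
#'   Deleted motif positions become holes (masked grid cells).
#' @param relaxed_leucine Match consensus L against \{L,I,V,F,M\}; default TRUE.
#' @param sequence_id Identifier recorded in the annotation.
#' @return An object of class `"lrr_repeats"`: list with `sequence_id`,
#'   `sequence`, `motif`, `repeats` (list of integer vectors, one per
#'   repeat, motif position -> 0-based sequence index, `NA` = hole) and
#'   `flags` (`"regular"`, `"irregular"` or `"curated"` per repeat).
#' @examples
#' m <- lrr_motif("lrr24")
#' s <- perfect_repeat_sequence(m, 3, seed = 1)
#' detect_repeats(s, m)
#' @export
detect_repeats <- function(sequence, motif = lrr_motif(),
                           min_match_fraction = 0.6, indel_budget = 2L,
                           relaxed_leucine = TRUE, sequence_id = "query") {
  if (!inherits(motif, "lrr_motif")) motif <- lrr_motif(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            min_match_fraction > 0, min_match_fraction <= 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(.AA20, "X")))
    stop("sequence contains non-residue characters: ",
         paste(unique(chars[!chars %in% c(.AA20, "X")]), collapse = ", "))
  n <- length(chars)
  m <- motif$length
  if (n < m) stop("sequence (", n, " aa) is shorter than one motif length (", m, ")")

  indel_budget <- as.integer(indel_budget)
  matchmat <- .token_match_matrix(chars, motif, relaxed_leucine)
  consensus <- vapply(motif$tokens, function(t) t$type != "wild", TRUE)
  n_cons <- sum(consensus)

  repeats <- list(); flags <- character(0)
  pos <- 1L
  while (pos <= n - (m - indel_budget) + 1L) {
    hit <- .match_motif_at(pos, n, matchmat, consensus, m, indel_budget)
    if (!is.null(hit) && hit$matches / n_cons >= min_match_fraction) {
      repeats[[length(repeats) + 1L]] <- hit$mapping
      flags <- c(flags, if (hit$indels == 0L) "regular" else "irregular")
      pos <- pos + hit$consumed
    } else {
      pos <- pos + 1L
    }
  }
  if (length(repeats) == 0L)
    warning("no repeats matching the motif found in '", sequence_id, "'")
  ann <- structure(list(sequence_id = sequence_id, sequence = sequence,
                        motif = motif, repeats = repeats, flags = flags,
                        params = list(min_match_fraction = min_match_fraction,
                                      indel_budget = indel_budget,
                                      relaxed_leucine = relaxed_leucine)),
                   class = "lrr_repeats")
  .validate_repeat_order(ann)
  ann
}

# mapped indices must be strictly increasing within and across repeats
.validate_repeat_order <- function(ann) {
  prev <- -1L
  for (r in seq_along(ann$repeats)) {
    idx <- ann$repeats[[r]]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    if (any(diff(idx) <= 0L) || idx[1] <= prev)
      stop("repeat ", r, " breaks the monotone sequence-index ordering")
    if (any(idx < 0L) || any(idx >= nchar(ann$sequence)))
      stop("repeat ", r, " maps outside the sequence")
    prev <- idx[length(idx)]
  }
  invisible(TRUE)
}

#' @export
print.lrr_repeats <- function(x, ...) {
  cat("LRR repeat annotation for '", x$sequence_id, "' (",
      nchar(x$sequence), " aa)\n", sep = "")
  cat("  repeats: ", length(x$repeats), sep = "")
  if (length(x$flags))
    cat("  [", paste(sprintf("%d %s", table(x$flags), names(table(x$flags))),
                     collapse = ", "), "]", sep = "")
  cat("\n  motif: ", x$motif$text, "\n", sep = "")
  invisible(x)
}

#' Apply hand-curation to a repeat annotation
#'
#' Repeat models from automatic detection often need manual correction
#' around irregular repeats. Each curation row overwrites one cell of the
#' motif-position to sequence-index mapping; affected repeats are flagged
#' `"curated"` and the monotone ordering invariant is re-validated.
#'
#' @param annotation An [detect_repeats()] result.
#' @param curation A data.frame with columns `seq_id`, `repeat_index`,
#'   `motif_position`, `seq_index` (1-based; `NA` or `"-"` = hole), as
#'   read by [read_curation()].
#' @return The curated `"lrr_repeats"` object.
#' @export
apply_curation <- function(annotation, curation) {
  stopifnot(inherits(annotation, "lrr_repeats"), is.data.frame(curation))
  if (nrow(curation) == 0L) return(annotation)
  need <- c("seq_id", "repeat_index", "motif_position", "seq_index")
  if (!all(need %in% names(curation)))
    stop("curation table needs columns: ", paste(need, collapse = ", "))
  if (!all(curation$seq_id == annotation$sequence_id))
    stop("curation rows refer to unknown sequence id(s): ",
         paste(unique(setdiff(curation$seq_id, annotation$sequence_id)),
               collapse = ", "))
  si <- curation$seq_index
  if (is.character(si)) si[si == "-"] <- NA
  si <- as.integer(si)
  for (k in seq_len(nrow(curation))) {
    r <- as.integer(curation$repeat_index[k])
    p <- as.integer(curation$motif_position[k])
    if (r < 1L || r > length(annotation$repeats))
      stop("curation references non-existent repeat ", r)
    if (p < 1L || p > annotation$motif$length)
      stop("curation references motif position ", p, " outside 1..",
           annotation$motif$length)
    annotation$repeats[[r]][p] <- si[k] - 1L   # to 0-based; NA stays NA
    annotation$flags[r] <- "curated"
  }
  .validate_repeat_order(annotation)
  annotation
}

#' Write / read a repeat annotation as TSV
#'
#' One row per (repeat, motif position) cell; `seq_index` is 1-based with
#' `"-"` marking holes. The same format serves as a curation table.
#'
#' @param annotation An `"lrr_repeats"` object.
#' @param path File path.
#' @export
write_repeat_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "lrr_repeats"))
  rows <- do.call(rbind, lapply(seq_along(annotation$repeats), function(r) {
    idx <- annotation$repeats[[r]]
    data.frame(seq_id = annotation$sequence_id, repeat_index = r,
               motif_position = seq_along(idx),
               seq_index = ifelse(is.na(idx), "-", as.character(idx + 1L)),
               flag = annotation$flags[r])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_repeat_annotation
#' @param sequence,sequence_id,motif Context needed to rebuild the full
#'   annotation object from the table.
#' @export
read_repeat_annotation <- function(path, sequence, motif = lrr_motif(),
                                   sequence_id = NULL) {
  if (!inherits(motif, "lrr_motif")) motif <- lrr_motif(motif)
  tab <- utils::read.delim(path, colClasses = "character")
  if (is.null(sequence_id)) sequence_id <- tab$seq_id[1]
  tab <- tab[tab$seq_id == sequence_id, , drop = FALSE]
  rs <- sort(unique(as.integer(tab$repeat_index)))
  repeats <- lapply(rs, function(r) {
    sub <- tab[as.integer(tab$repeat_index) == r, ]
    idx <- rep(NA_integer_, motif$length)
    pos <- as.integer(sub$motif_position)
    val <- ifelse(sub$seq_index == "-", NA, sub$seq_index)
    idx[pos] <- as.integer(val) - 1L
    idx
  })
  flags <- vapply(rs, function(r)
    tab$flag[as.integer(tab$repeat_index) == r][1], "")
  ann <- structure(list(sequence_id = sequence_id,
                        sequence = toupper(sequence), motif = motif,
                        repeats = repeats, flags = flags,
                        params = list()),
                   class = "lrr_repeats")
  .validate_repeat_order(ann)
  ann
}

#' Read a curation table TSV
#'
#' @param path TSV with columns `seq_id`, `repeat_index`, `motif_position`,
#'   `seq_index` (1-based, `"-"` = hole).
#' @return data.frame suitable for [apply_curation()].
#' @export
read_curation <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  tab$repeat_index <- as.integer(tab$repeat_index)
  tab$motif_position <- as.integer(tab$motif_position)
  tab
}
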