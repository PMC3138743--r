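#' Repeat conservation mapping of an LRR domain family
#'
#' The full mapping pipeline: detect (and optionally hand-curate) the
#' repeats of the reference sequence against a consensus motif; align the
#' family (or ingest a pre-computed alignment); lay the solvent-exposed
#' variable positions on a repeats-by-positions surface grid; score each
#' cell's conservation across all homolog pairs (raw substitution-matrix
#' units and normalized to \[0,1\]); and smooth with a center-weighted
#' sliding window into the regional conservation map that is rendered as a
#' heat map. When ligand-contact annotations are supplied the decile
#' enrichment statistics and the contact-vs-other Student's t-test are
#' computed as well.
#'
#' @param sequences Named character vector of >= 2 homologous LRR domain
#'   sequences, a FASTA path, or an [generate_family()] result.
#' @param motif Consensus motif: preset `"lrr24"` (default) or `"plant"`,
#'   motif text, or an [lrr_motif()].
#' @param reference Id of the sequence whose repeats define the grid;
#'   default the first record.
#' @param aligned Input is already aligned (gaps allowed, equal lengths).
#' @param matrix Substitution matrix id (`"blosum62"`, `"blosum65"`) or an
#'   [rcm_matrix()].
#' @param kernel Sliding-window kernel; default the center-weighted 5x5
#'   window of [make_kernel()].
#' @param min_match_fraction,indel_budget,relaxed_leucine Repeat-detection
#'   parameters; see [detect_repeats()].
#' @param gap_policy `"score"` (gap pairs count as maximally divergent) or
#'   `"exclude"`.
#' @param curation Optional curation table ([read_curation()] format).
#' @param contacts Optional ligand-contact cells (data.frame with
#'   `repeat_index`, `motif_position`) to evaluate against.
#' @param direction `"conserved"` or `"divergent"` (affects ranking and
#'   rendering only; divergence mode is used when comparing paralogs with
#'   diversified specificities).
#' @param verbose Log one line per pipeline stage to stderr.
#' @param seed Optional integer recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return An object of class `"rcm"` with components `motif`,
#'   `annotation`, `alignment`, `cellmap`, `raw`, `weighted`, `regional`
#'   (all `"rcm_grid"`s), `kernel`, `evaluation` (when contacts given) and
#'   `config`. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' fam <- generate_family(lrr_family_spec(n_repeats = 12, seed = 7))
#' fit <- rcm(fam, contacts = fam$patch)
#' summary(fit)
#' @export
rcm <- function(sequences, motif = lrr_motif(), reference = NULL,
                aligned = FALSE, matrix = "blosum62",
                kernel = make_kernel(), min_match_fraction = 0.6,
                indel_budget = 2L, relaxed_leucine = TRUE,
                gap_policy = c("score", "exclude"),
                curation = NULL, contacts = NULL,
                direction = c("conserved", "divergent"),
                verbose = FALSE, seed = NULL) {
  cl <- match.call()
  gap_policy <- match.arg(gap_policy)
  direction <- match.arg(direction)
  log <- function(...) if (verbose) message("[rcm] ", sprintf(...))

  if (inherits(sequences, "lrr_family")) sequences <- sequences$sequences
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences))
    sequences <- read_sequences(sequences, aligned = aligned)
  if (length(sequences) < 2L)
    stop("input stage: RCM requires at least two homologous sequences")
  if (!inherits(motif, "lrr_motif")) motif <- lrr_motif(motif)
  if (!inherits(matrix, "rcm_submat")) matrix <- rcm_matrix(matrix)
  if (is.null(reference)) reference <- names(sequences)[1]

  # align / ingest
  alignment <- if (aligned) {
    load_alignment(sequences, reference = reference)
  } else {
    align_family(sequences, matrix = matrix, reference = reference)
  }
  log("alignment: %d sequences, %d columns", length(alignment$ids),
      nchar(alignment$aligned[1]))

  # detect + curate repeats on the ungapped reference
  refseq <- gsub("-", "", sequences[[reference]], fixed = TRUE)
  annotation <- detect_repeats(refseq, motif,
                               min_match_fraction = min_match_fraction,
                               indel_budget = indel_budget,
                               relaxed_leucine = relaxed_leucine,
                               sequence_id = reference)
  if (!is.null(curation)) annotation <- apply_curation(annotation, curation)
  if (length(annotation$repeats) == 0L)
    stop("repeat detection stage: no repeats matching the motif in '",
         reference, "'")
  log("repeats: %d detected in reference '%s'", length(annotation$repeats),
      reference)

  cellmap <- map_cells_to_columns(annotation, alignment)
  log("grid: %d x %d cells (%d masked)", nrow(cellmap), ncol(cellmap),
      sum(is.na(cellmap)))

  raw <- score_grid(alignment, cellmap, matrix, mode = "raw",
                    gap_policy = gap_policy)
  weighted <- score_grid(alignment, cellmap, matrix, mode = "weighted",
                         gap_policy = gap_policy)
  regional <- regional_map(weighted, kernel)
  log("scores: raw/weighted/regional computed (matrix %s, kernel %s)",
      matrix$matrix_id, kernel$preset)

  evaluation <- NULL
  if (!is.null(contacts)) {
    evaluation <- contact_enrichment(
      list(raw = raw, weighted = weighted, regional = regional), contacts)
    log("evaluation: %d contact cells, top-decile fraction %.3f (regional)",
        evaluation$n_contact, evaluation$top_decile_fraction[["regional"]])
  }

  structure(list(call = cl, input_sequences = sequences, motif = motif,
                 matrix_id = matrix$matrix_id, kernel = kernel,
                 annotation = annotation, alignment = alignment,
                 cellmap = cellmap, raw = raw, weighted = weighted,
                 regional = regional, contacts = contacts,
                 curation = curation, evaluation = evaluation,
                 direction = direction,
                 config = list(aligned = aligned, gap_policy = gap_policy,
                               min_match_fraction = min_match_fraction,
                               indel_budget = as.integer(indel_budget),
                               relaxed_leucine = relaxed_leucine,
                               seed = seed)),
            class = "rcm")
}

#' @export
print.rcm <- function(x, ...) {
  cat("Repeat conservation map\n")
  cat("  reference: ", x$alignment$reference_id, " (",
      length(x$annotation$repeats), " repeats, motif ", x$motif$text, ")\n",
      sep = "")
  cat("  family: ", length(x$alignment$ids), " sequences; matrix ",
      x$matrix_id, "; kernel ", x$kernel$preset, " ", x$kernel$size, "x",
      x$kernel$size, "\n", sep = "")
  rng <- range(x$regional$scores, na.rm = TRUE)
  cat(sprintf("  regional scores: %d x %d grid, range [%.3f, %.3f]\n",
              nrow(x$regional$scores), ncol(x$regional$scores),
              rng[1], rng[2]))
  if (!is.null(x$evaluation))
    cat(sprintf("  contact enrichment: %.0f%% of %d contacts in top decile (regional)\n",
                100 * x$evaluation$top_decile_fraction[["regional"]],
                x$evaluation$n_contact))
  invisible(x)
}

#' @export
summary.rcm <- function(object, n_top = 5L, ...) {
  rk <- rank_cells(object$regional, object$direction)
  top <- utils::head(rk, n_top)
  beta <- sort(object$motif$beta_columns)
  inb <- top$motif_position %in% beta
  top$label <- paste0(top$repeat_index, ":", top$motif_position)
  if (any(inb))
    top$label[inb] <- cell_label(top$repeat_index[inb],
                                 match(top$motif_position[inb], beta))
  out <- list(rcm = object, top_cells = top,
              n_unmasked = sum(!is.na(object$regional$scores)),
              score_summary = summary(as.vector(object$regional$scores)))
  class(out) <- "summary.rcm"
  out
}

#' @export
print.summary.rcm <- function(x, ...) {
  print(x$rcm)
  cat("  unmasked cells:", x$n_unmasked, "\n")
  cat("  regional score distribution:\n")
  print(x$score_summary)
  cat("  top cells (", x$rcm$direction, " direction; label = repeat.beta-position):\n",
      sep = "")
  print(x$top_cells, row.names = FALSE)
  if (!is.null(x$rcm$evaluation)) print(x$rcm$evaluation)
  invisible(x)
}

#' @export
as.data.frame.rcm <- function(x, ...) {
  s <- x$regional$scores
  idx <- expand.grid(row = seq_len(nrow(s)), col = seq_len(ncol(s)))
  dec <- tryCatch(decile_assign(x$regional), error = function(e) NULL)
  df <- data.frame(
    repeat_index = as.integer(rownames(s)[idx$row]),
    motif_position = as.integer(colnames(s)[idx$col]),
    beta = as.integer(colnames(s)[idx$col]) %in% x$motif$beta_columns,
    raw = x$raw$scores[cbind(idx$row, idx$col)],
    weighted = x$weighted$scores[cbind(idx$row, idx$col)],
    regional = s[cbind(idx$row, idx$col)]
  )
  if (!is.null(dec)) df$decile <- dec[cbind(idx$row, idx$col)]
  if (!is.null(x$contacts))
    df$contact <- paste(df$repeat_index, df$motif_position) %in%
      paste(x$contacts$repeat_index, x$contacts$motif_position)
  df[order(df$repeat_index, df$motif_position), ]
}

#' Heat-map of a repeat conservation map
#'
#' Rows are repeats (N-terminal at the top), columns are variable motif
#' positions. Red marks the most conserved regions, blue the most
#' divergent (reversed in divergence mode); bold vertical lines delineate
#' the five beta-strand/beta-turn columns; contact cells are overlaid as
#' white asterisks; masked cells are grey.
#'
#' @param x An `"rcm"` object.
#' @param stage `"regional"` (default), `"weighted"` or `"raw"`.
#' @param absolute_scale Use a fixed \[0,1\] color scale instead of the
#'   map's observed range (weighted/regional stages only).
#' @param show_contacts Overlay contact asterisks when available.
#' @param main Plot title.
#' @param ... Ignored.
#' @export
plot.rcm <- function(x, stage = c("regional", "weighted", "raw"),
                     absolute_scale = FALSE, show_contacts = TRUE,
                     main = NULL, ...) {
  stage <- match.arg(stage)
  s <- x[[stage]]$scores
  nr <- nrow(s); nc <- ncol(s)
  pal <- grDevices::colorRampPalette(
    c("#08306B", "#4292C6", "#F7F7F7", "#EF6548", "#7F0000"))(255)
  if (x$direction == "divergent") pal <- rev(pal)
  zlim <- if (absolute_scale && stage != "raw") c(0, 1)
          else range(s, na.rm = TRUE)
  if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
  if (is.null(main))
    main <- sprintf("RCM %s map (%s, %s kernel)", stage, x$matrix_id,
                    x$kernel$preset)
  op <- graphics::par(mar = c(2, 4, 5, 2))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                        xaxs = "i", yaxs = "i")
  graphics::rect(0.5, 0.5, nc + 0.5, nr + 0.5, col = "grey70", border = NA)
  # row 1 (N-terminal repeat) at the top
  graphics::image(seq_len(nc), seq_len(nr), t(s[nr:1, , drop = FALSE]),
                  zlim = zlim, col = pal, add = TRUE, useRaster = FALSE)
  graphics::axis(3, at = seq_len(nc), labels = colnames(s), tick = FALSE,
                 cex.axis = 0.8, line = -0.5)
  graphics::axis(2, at = nr:1, labels = rownames(s), las = 1, tick = FALSE,
                 cex.axis = 0.8)
  graphics::mtext("LRR consensus position", side = 3, line = 2)
  graphics::mtext("repeat", side = 2, line = 2.5)
  graphics::title(main, line = 3.2)
  bcols <- sort(match(x$motif$beta_columns, as.integer(colnames(s))))
  bcols <- bcols[!is.na(bcols)]
  if (length(bcols))
    graphics::rect(min(bcols) - 0.5, 0.5, max(bcols) + 0.5, nr + 0.5,
                   border = "black", lwd = 3)
  if (show_contacts && !is.null(x$contacts)) {
    ci <- match(as.character(x$contacts$motif_position), colnames(s))
    ri <- match(as.character(x$contacts$repeat_index), rownames(s))
    graphics::text(ci, nr + 1 - ri, "*", col = "white", cex = 1.6, font = 2)
  }
  graphics::box()
  invisible(x)
}
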