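# File I/O: FASTA / Clustal input, TSV score grids, the JSON run manifest,
# and PNG heat-map rendering.

#' Read protein sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header and must be
#' unique; residues are upper-cased and a trailing `*` is stripped.
#'
#' @param path FASTA file.
#' @param aligned Allow `-` gap characters (aligned FASTA).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path, aligned = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- ids
  if (!aligned && any(grepl("-", seqs, fixed = TRUE)))
    stop("gap characters found in '", path,
         "'; if this is an alignment, read it with aligned = TRUE")
  seqs
}

#' Write sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    cat(">", id, "\n", sep = "", file = con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`; default guessed from the
#'   extension (`.aln` = Clustal).
#' @param reference Reference id passed to [load_alignment()].
#' @return An `"lrr_alignment"`.
#' @export
read_alignment <- function(path, format = NULL, reference = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.aln$", path, ignore.case = TRUE)) "clustal" else "fasta"
  format <- match.arg(format, c("fasta", "clustal"))
  recs <- if (format == "clustal") {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    as.character(Biostrings::unmasked(ma))
  } else {
    read_sequences(path, aligned = TRUE)
  }
  load_alignment(recs, reference = reference)
}

#' Write / read a score grid as TSV
#'
#' Rows are repeats, columns are variable motif positions (the header row
#' carries the motif position numbers); masked cells are `NA`. Scores are
#' written with full precision so a round trip is exact.
#'
#' @param grid An `"rcm_grid"`.
#' @param path File path.
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "rcm_grid"))
  s <- grid$scores
  txt <- matrix(ifelse(is.na(s), "NA", formatC(s, digits = 17, format = "g")),
                nrow(s), ncol(s))
  df <- data.frame(repeat_index = rownames(s), txt, check.names = FALSE)
  names(df) <- c("repeat_index", colnames(s))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @param mode Score mode recorded on the re-read grid.
#' @export
read_grid_tsv <- function(path, mode = "weighted") {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  rn <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  s <- matrix(as.numeric(ifelse(m == "NA", NA, m)), nrow(m),
              dimnames = list(rn, colnames(m)))
  structure(list(scores = s, mode = mode, matrix_id = NULL, gap_policy = NULL),
            class = "rcm_grid")
}

#' Render a regional map as a heat-map image
#'
#' Writes a PNG (or SVG, by extension) of the map drawn by [plot.rcm()]:
#' red = most conserved, blue = most divergent, beta-region columns
#' outlined in bold, ligand contacts overlaid as white asterisks, masked
#' cells grey.
#'
#' @param x An `"rcm"` object.
#' @param file Output path ending in `.png` or `.svg`.
#' @param width,height Device size in pixels (PNG) or inches (SVG).
#' @param ... Passed to [plot.rcm()].
#' @export
render_heatmap <- function(x, file, width = 800, height = 800, ...) {
  if (grepl("\\.svg$", file, ignore.case = TRUE)) {
    grDevices::svg(file, width = width / 100, height = height / 100)
  } else {
    grDevices::png(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  plot(x, ...)
  invisible(file)
}

.rcm_version <- function() as.character(utils::packageVersion("rcmap"))

#' Write a complete RCM run to an output directory
#'
#' Emits the input sequences, the final alignment (aligned FASTA), the
#' three score TSVs (raw, weighted, regional), the heat-map PNG, the
#' evaluation report (when contacts were supplied) and a JSON manifest
#' sufficient to re-run the map bit-identically via [rcm_from_manifest()].
#'
#' @param x An `"rcm"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_rcm <- function(x, dir) {
  stopifnot(inherits(x, "rcm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa_in <- file.path(dir, "input_sequences.fasta")
  write_fasta(x$input_sequences, fa_in)
  write_fasta(x$alignment$aligned, file.path(dir, "alignment.fasta"))
  write_grid_tsv(x$raw, file.path(dir, "cell_scores_raw.tsv"))
  write_grid_tsv(x$weighted, file.path(dir, "cell_scores_weighted.tsv"))
  write_grid_tsv(x$regional, file.path(dir, "regional_scores.tsv"))
  render_heatmap(x, file.path(dir, "heatmap.png"))
  if (!is.null(x$contacts))
    write_contacts(x$contacts, file.path(dir, "contacts.tsv"))
  if (!is.null(x$curation))
    utils::write.table(x$curation, file.path(dir, "curation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$evaluation)) {
    ev <- x$evaluation
    jsonlite::write_json(
      list(histogram = as.data.frame(ev$histogram),
           top_decile_fraction = as.list(ev$top_decile_fraction),
           top_two_decile_fraction = as.list(ev$top_two_decile_fraction),
           n_contact = ev$n_contact, n_other = ev$n_other,
           ttest = ev$ttest),
      file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    tool = "rcmap", version = .rcm_version(),
    input = list(file = "input_sequences.fasta",
                 md5 = unname(tools::md5sum(fa_in))),
    aligned = x$config$aligned,
    motif = x$motif$text,
    matrix_id = x$matrix_id,
    kernel = list(preset = x$kernel$preset, size = x$kernel$size,
                  sigma = x$kernel$sigma),
    gap_policy = x$config$gap_policy,
    edge_policy = "renormalize",
    reference_id = x$alignment$reference_id,
    min_match_fraction = x$config$min_match_fraction,
    indel_budget = x$config$indel_budget,
    relaxed_leucine = x$config$relaxed_leucine,
    direction = x$direction,
    contacts = if (!is.null(x$contacts)) "contacts.tsv",
    curation = if (!is.null(x$curation)) "curation.tsv",
    seed = x$config$seed
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mpath)
}

#' Re-run an RCM map from its manifest
#'
#' Reads the manifest and the input files it references and recomputes the
#' map with the recorded configuration, reproducing all score TSVs
#' bit-identically.
#'
#' @param manifest Path to a `manifest.json` written by [write_rcm()].
#' @return An `"rcm"` object.
#' @export
rcm_from_manifest <- function(manifest) {
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  seqs <- read_sequences(file.path(dir, mf$input$file), aligned = isTRUE(mf$aligned))
  contacts <- if (!is.null(mf$contacts)) read_contacts(file.path(dir, mf$contacts))
  curation <- if (!is.null(mf$curation)) read_curation(file.path(dir, mf$curation))
  kernel <- make_kernel(mf$kernel$preset, mf$kernel$size,
                        sigma = if (!is.null(mf$kernel$sigma)) mf$kernel$sigma else 1)
  rcm(seqs, motif = mf$motif, reference = mf$reference_id,
      aligned = isTRUE(mf$aligned), matrix = mf$matrix_id, kernel = kernel,
      min_match_fraction = mf$min_match_fraction,
      indel_budget = mf$indel_budget,
      relaxed_leucine = isTRUE(mf$relaxed_leucine),
      gap_policy = mf$gap_policy, curation = curation,
      contacts = contacts, direction = mf$direction)
}
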