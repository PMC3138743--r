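# Validation machinery: decile assignment of ranked scores, enrichment of
# annotated ligand-contact cells per score stage, and the contact-vs-other
# Student's t-test.

#' Assign deciles to the unmasked cells of a map
#'
#' Scores are arranged in descending order (positional tie-break) and
#' divided into tenths: the cell at rank r of n gets decile
#' `ceiling(10 r / n)`, so decile 1 holds the highest scores and decile
#' sizes differ by at most one.
#'
#' @param map An `"rcm_grid"`.
#' @return Integer matrix of deciles, same shape/mask as the score grid.
#' @export
decile_assign <- function(map) {
  stopifnot(inherits(map, "rcm_grid"))
  n <- sum(!is.na(map$scores))
  if (n < 10L) stop("decile assignment needs at least 10 unmasked cells")
  rk <- rank_cells(map, "conserved")
  out <- matrix(NA_integer_, nrow(map$scores), ncol(map$scores),
                dimnames = dimnames(map$scores))
  rows <- match(as.character(rk$repeat_index), rownames(out))
  cols <- match(as.character(rk$motif_position), colnames(out))
  out[cbind(rows, cols)] <- as.integer(ceiling(10 * rk$rank / n))
  out
}

.contact_matrix_index <- function(map, contacts) {
  stopifnot(is.data.frame(contacts),
            all(c("repeat_index", "motif_position") %in% names(contacts)))
  if (nrow(contacts) == 0L) stop("contact set is empty")
  rows <- match(as.character(contacts$repeat_index), rownames(map$scores))
  cols <- match(as.character(contacts$motif_position), colnames(map$scores))
  if (anyNA(rows) || anyNA(cols))
    stop("contact cells outside the grid: ",
         paste(contacts$repeat_index[is.na(rows) | is.na(cols)],
               contacts$motif_position[is.na(rows) | is.na(cols)],
               sep = ".", collapse = ", "))
  ij <- cbind(rows, cols)
  if (anyNA(map$scores[ij]))
    stop("contact cells fall on masked grid cells")
  ij
}

#' Contact-cell enrichment across score stages
#'
#' For each score stage (typically raw, weighted and regional), tallies
#' how many annotated ligand-contact cells fall into each decile of that
#' stage's descending score ranking, and reports the top-decile and
#' top-two-decile contact fractions. This is the statistic used to compare
#' the three scoring stages: on real LRR validation families the contact
#' fraction in the top decile grows from raw to weighted to regional
#' scores.
#'
#' @param stages Named list of `"rcm_grid"` objects sharing shape and mask.
#' @param contacts data.frame with `repeat_index`, `motif_position`.
#' @return Object of class `"rcm_enrichment"`: `histogram` (stages x 10
#'   contact counts), `top_decile_fraction`, `top_two_decile_fraction`,
#'   `n_contact`, `n_other`, and `ttest` (on the last stage).
#' @export
contact_enrichment <- function(stages, contacts) {
  stopifnot(is.list(stages), length(stages) >= 1L)
  if (is.null(names(stages))) names(stages) <- paste0("stage", seq_along(stages))
  hist <- matrix(0L, nrow = length(stages), ncol = 10L,
                 dimnames = list(names(stages), paste0("decile", 1:10)))
  top1 <- top2 <- stats::setNames(numeric(length(stages)), names(stages))
  for (s in seq_along(stages)) {
    map <- stages[[s]]
    ij <- .contact_matrix_index(map, contacts)
    dec <- decile_assign(map)[ij]
    hist[s, ] <- tabulate(dec, 10L)
    top1[s] <- hist[s, 1] / nrow(contacts)
    top2[s] <- sum(hist[s, 1:2]) / nrow(contacts)
  }
  last <- stages[[length(stages)]]
  ij <- .contact_matrix_index(last, contacts)
  tt <- tryCatch(contact_ttest(last, contacts), error = function(e) NULL)
  structure(list(histogram = hist,
                 top_decile_fraction = top1,
                 top_two_decile_fraction = top2,
                 n_contact = nrow(contacts),
                 n_other = sum(!is.na(last$scores)) - nrow(contacts),
                 ttest = tt),
            class = "rcm_enrichment")
}

#' @export
print.rcm_enrichment <- function(x, ...) {
  cat("Contact-cell decile enrichment (", x$n_contact, " contact / ",
      x$n_other, " other cells)\n", sep = "")
  print(x$histogram)
  cat("top-decile fraction:    ",
      paste(sprintf("%s %.3f", names(x$top_decile_fraction),
                    x$top_decile_fraction), collapse = ", "), "\n")
  cat("top-two-decile fraction:",
      paste(sprintf("%s %.3f", names(x$top_two_decile_fraction),
                    x$top_two_decile_fraction), collapse = ", "), "\n")
  if (!is.null(x$ttest))
    cat(sprintf("contact vs other (final stage): t = %.3f, one-sided p = %.3g\n",
                x$ttest$t_statistic, x$ttest$p_value))
  invisible(x)
}

#' Student's t-test of contact vs non-contact scores
#'
#' Two-sample pooled-variance Student's t-test with the one-sided
#' alternative that contact cells score higher than the remaining cells;
#' the two-sided p-value is reported alongside for transparency.
#'
#' @param map An `"rcm_grid"` (typically the regional map).
#' @param contacts data.frame with `repeat_index`, `motif_position`.
#' @return List with `t_statistic`, `p_value` (one-sided), `p_two_sided`,
#'   `n_contact`, `n_other`.
#' @export
contact_ttest <- function(map, contacts) {
  ij <- .contact_matrix_index(map, contacts)
  all_mask <- matrix(FALSE, nrow(map$scores), ncol(map$scores))
  all_mask[ij] <- TRUE
  x <- map$scores[ij]
  y <- map$scores[!all_mask & !is.na(map$scores)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 contact and 2 non-contact cells")
  tt <- stats::t.test(x, y, alternative = "greater", var.equal = TRUE)
  list(t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       p_two_sided = stats::t.test(x, y, var.equal = TRUE)$p.value,
       n_contact = length(x), n_other = length(y))
}

#' Read / write a contact annotation TSV
#'
#' Columns `repeat_index`, `motif_position` (both 1-based), matching the
#' asterisk overlay of validation maps and the ground-truth patch emitted
#' by [generate_family()].
#'
#' @param path File path.
#' @export
read_contacts <- function(path) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("repeat_index", "motif_position") %in% names(tab)))
  tab$repeat_index <- as.integer(tab$repeat_index)
  tab$motif_position <- as.integer(tab$motif_position)
  tab
}

#' @rdname read_contacts
#' @param contacts data.frame with `repeat_index`, `motif_position`.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts[, c("repeat_index", "motif_position")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
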