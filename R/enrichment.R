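#' Collapse a classification into unique-fragment read counts
#'
#' Natural-frame reads are collapsed to unique displayed fragments,
#' identified by their residue span on the fusion protein, with
#' read-count weights.  Only natural-frame clones enter downstream
#' enrichment statistics: they are the population actually displaying
#' authentic antigen fragments.
#'
#' @param x A `classification` from [classify_library()] or its
#'   `fragments` data frame.
#' @param library_id `"unselected"` or `"selected"` (free text allowed).
#' @return Object of class `library_counts`: list with `library_id`,
#'   `fragments` (`data.frame` of `res_start`, `res_end`, `count`) and
#'   `total_natural_reads`.
#' @export
library_counts <- function(x, library_id = "unselected") {
  if (inherits(x, "classification")) x <- x$fragments
  nat <- x[x$frame_class == "natural" & !is.na(x$res_start), , drop = FALSE]
  if (nrow(nat)) {
    key <- paste(nat$res_start, nat$res_end, sep = "-")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "-", fixed = TRUE))
    frag <- data.frame(res_start = as.integer(parts[, 1]),
                       res_end = as.integer(parts[, 2]),
                       count = as.integer(tab), stringsAsFactors = FALSE)
    frag <- frag[order(frag$res_start, frag$res_end), , drop = FALSE]
    rownames(frag) <- NULL
  } else {
    frag <- data.frame(res_start = integer(), res_end = integer(),
                       count = integer())
  }
  structure(list(library_id = library_id, fragments = frag,
                 total_natural_reads = sum(frag$count)),
            class = "library_counts")
}

#' @export
print.library_counts <- function(x, ...) {
  cat("<library_counts> ", x$library_id, ": ", nrow(x$fragments),
      " unique fragments, ", x$total_natural_reads,
      " natural-frame reads\n", sep = "")
  invisible(x)
}

# raw per-residue read tally C[i] = sum of counts of fragments covering i,
# by difference-array accumulation
residue_tallies <- function(counts, L) {
  stopifnot(inherits(counts, "library_counts"))
  inc <- numeric(L + 1L)
  f <- counts$fragments
  if (nrow(f)) {
    s <- rowsum(as.numeric(f$count), f$res_start)
    inc[as.integer(rownames(s))] <- inc[as.integer(rownames(s))] + s[, 1]
    e <- rowsum(as.numeric(f$count), f$res_end + 1L)
    inc[as.integer(rownames(e))] <- inc[as.integer(rownames(e))] - e[, 1]
  }
  cumsum(inc)[seq_len(L)]
}

#' Per-residue occurrence profile
#'
#' For each residue of the fusion protein, the number of natural-frame
#' reads whose displayed fragment covers that residue, normalised by the
#' library's total natural-frame reads.
#'
#' @param counts A [library_counts()].
#' @param ref A [reference_antigen()].
#' @return Numeric vector of length `nchar(ref$protein)`, values in
#'   `[0, 1]`.
#' @export
residue_occurrence <- function(counts, ref) {
  stopifnot(inherits(ref, "reference_antigen"))
  if (counts$total_natural_reads <= 0L)
    stop("library has zero natural-frame reads: occurrence undefined")
  L <- nchar(ref$protein)
  residue_tallies(counts, L) / counts$total_natural_reads
}

#' Per-residue enrichment factor
#'
#' The enrichment factor at residue `i` is the ratio of the residue's
#' occurrence in the affinity-selected library to its occurrence in the
#' unselected library, after adding a pseudocount (default 1) to the raw
#' per-residue read tallies:
#' \deqn{EF_i = \frac{(C^{sel}_i + p)/N_{sel}}{(C^{unsel}_i + p)/N_{unsel}}}
#' where `C` are per-residue read tallies and `N` the libraries' total
#' natural-frame reads.  The pseudocount keeps the profile finite and
#' strictly positive everywhere; residues covered in neither library sit
#' at the defined baseline `N_unsel / N_sel`.  With
#' `normalize = FALSE` the depth normalisation is omitted and
#' `EF_i = (C^{sel}_i + p) / (C^{unsel}_i + p)`.
#'
#' @param sel,unsel [library_counts()] for the selected and unselected
#'   libraries.
#' @param ref A [reference_antigen()].
#' @param pseudocount Pseudocount added to each residue tally
#'   (default 1).
#' @param normalize Divide tallies by library depth (default `TRUE`).
#' @return Object of class `residue_enrichment_profile`: a `data.frame`
#'   with columns `residue`, `occ_unselected`, `occ_selected`, `ef`, and
#'   attributes `pseudocount`, `normalize`.
#' @export
enrichment_factor <- function(sel, unsel, ref, pseudocount = 1,
                              normalize = TRUE) {
  stopifnot(inherits(sel, "library_counts"),
            inherits(unsel, "library_counts"),
            inherits(ref, "reference_antigen"), pseudocount >= 0)
  if (sel$total_natural_reads <= 0L || unsel$total_natural_reads <= 0L)
    stop("both libraries must contain natural-frame reads")
  L <- nchar(ref$protein)
  Cs <- residue_tallies(sel, L)
  Cu <- residue_tallies(unsel, L)
  Ns <- sel$total_natural_reads
  Nu <- unsel$total_natural_reads
  ef <- if (normalize)
    ((Cs + pseudocount) / Ns) / ((Cu + pseudocount) / Nu)
  else
    (Cs + pseudocount) / (Cu + pseudocount)
  out <- data.frame(residue = seq_len(L),
                    occ_unselected = Cu / Nu,
                    occ_selected = Cs / Ns,
                    ef = ef)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "normalize") <- normalize
  class(out) <- c("residue_enrichment_profile", "data.frame")
  out
}

#' Rank fragments by selected-library frequency
#'
#' Unique fragments sorted by their frequency among natural-frame reads
#' of the selected library, descending.  Ties are broken in favour of
#' the longer span, then the smaller start residue.
#'
#' @param sel [library_counts()] of the selected library.
#' @param top_n How many fragments to return (default 30, the scale at
#'   which fragment panels are conventionally inspected); if larger than
#'   the number of unique fragments all are returned with a message.
#' @param unsel Optional unselected [library_counts()] used to annotate
#'   each fragment's unselected frequency.
#' @return `data.frame` with columns `rank`, `res_start`, `res_end`,
#'   `count`, `frequency_selected`, `frequency_unselected`.
#' @export
rank_fragments <- function(sel, top_n = 30L, unsel = NULL) {
  stopifnot(inherits(sel, "library_counts"), top_n >= 1L)
  f <- sel$fragments
  if (!nrow(f)) stop("selected library has no natural-frame fragments")
  f$frequency_selected <- f$count / sel$total_natural_reads
  len <- f$res_end - f$res_start + 1L
  ord <- order(-f$frequency_selected, -len, f$res_start)
  f <- f[ord, , drop = FALSE]
  if (top_n > nrow(f)) {
    message("top_n = ", top_n, " exceeds the ", nrow(f),
            " unique fragments; returning all")
    top_n <- nrow(f)
  }
  f <- f[seq_len(top_n), , drop = FALSE]
  f$frequency_unselected <- NA_real_
  if (!is.null(unsel)) {
    key <- paste(f$res_start, f$res_end)
    ukey <- paste(unsel$fragments$res_start, unsel$fragments$res_end)
    m <- match(key, ukey)
    f$frequency_unselected <-
      ifelse(is.na(m), 0,
             unsel$fragments$count[m] / unsel$total_natural_reads)
  }
  f$rank <- seq_len(nrow(f))
  rownames(f) <- NULL
  f[, c("rank", "res_start", "res_end", "count",
        "frequency_selected", "frequency_unselected")]
}

#' Call significantly enriched fragments (mean + 5 SD rule)
#'
#' A fragment is significantly enriched when its frequency among
#' natural-frame reads of the selected library exceeds the mean plus
#' five sample standard deviations of the frequency distribution over
#' unique fragments of the unselected library.
#'
#' @param sel,unsel [library_counts()] for the two libraries.
#' @param n_sd Number of standard deviations above the mean (default 5).
#' @return `data.frame` with columns `res_start`, `res_end`,
#'   `frequency_selected`, `frequency_unselected`, `significant`;
#'   attribute `threshold` holds the frequency cutoff.
#' @export
call_significant <- function(sel, unsel, n_sd = 5) {
  stopifnot(inherits(sel, "library_counts"),
            inherits(unsel, "library_counts"))
  fu <- unsel$fragments$count / unsel$total_natural_reads
  if (length(fu) < 2L)
    stop("unselected library has fewer than 2 unique fragments; the ",
         "frequency standard deviation is undefined - sequence a larger ",
         "unselected library")
  threshold <- mean(fu) + n_sd * sd(fu)
  f <- sel$fragments
  out <- data.frame(res_start = f$res_start, res_end = f$res_end,
                    frequency_selected = f$count / sel$total_natural_reads,
                    stringsAsFactors = FALSE)
  key <- paste(f$res_start, f$res_end)
  ukey <- paste(unsel$fragments$res_start, unsel$fragments$res_end)
  m <- match(key, ukey)
  out$frequency_unselected <- ifelse(is.na(m), 0, fu[m])
  out$significant <- out$frequency_selected > threshold
  out <- out[order(-out$frequency_selected), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
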