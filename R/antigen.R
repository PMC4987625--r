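#' Reference antigen
#'
#' Container for the antigen every other stage maps against: the coding
#' sequence of the displayed fusion protein, its translation, the offset
#' between fusion-wide and antigen-local residue numbering, and optional
#' domain / antibody-contact annotation.
#'
#' Residue and nucleotide coordinates are 1-based and inclusive on both
#' ends throughout the package.  Antigen-local residue `r` corresponds to
#' fusion residue `r + numbering_offset`.
#'
#' @param name Antigen name.
#' @param cds Coding sequence (character, `ACGT`); length must be a
#'   multiple of 3 and must translate without internal stop codons.
#' @param protein Optional amino-acid sequence.  When omitted it is
#'   derived by translation with the standard genetic code; when given it
#'   must match the translation exactly.
#' @param numbering_offset Integer offset mapping antigen-local numbering
#'   to fusion numbering (`fusion = local + offset`).  Default 0.
#' @param domains Optional `data.frame` with columns `label`, `start`,
#'   `end` (fusion residue coordinates).
#' @param contact_points Optional integer vector of antigen-local residue
#'   numbers in crystallographic contact with the antibody.
#'
#' @return An object of class `reference_antigen`.
#' @seealso [load_reference()], [convert_span()], [contact_coverage()]
#' @export
reference_antigen <- function(name, cds, protein = NULL,
                              numbering_offset = 0L,
                              domains = NULL, contact_points = NULL) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    stop("cds contains characters other than A/C/G/T")
  if (nchar(cds) %% 3L != 0L)
    stop("cds length (", nchar(cds), ") is not divisible by 3")
  tr <- translate_cds(cds)
  stop_at <- stri_first_stop(tr)
  if (!is.na(stop_at))
    stop("internal stop codon at codon ", stop_at, " (nt ",
         3L * stop_at - 2L, "-", 3L * stop_at, ")")
  if (is.null(protein)) {
    protein <- tr
  } else {
    protein <- toupper(protein)
    if (nchar(protein) != nchar(tr))
      stop("protein length (", nchar(protein),
           ") does not equal cds length / 3 (", nchar(tr), ")")
    diffs <- which(strsplit(tr, "")[[1]] != strsplit(protein, "")[[1]])
    if (length(diffs))
      stop("translation of cds disagrees with supplied protein; first ",
           "discrepant codon is codon ", diffs[1], " (nt ",
           3L * diffs[1] - 2L, "-", 3L * diffs[1], ")")
  }
  L <- nchar(protein)
  if (!is.null(domains)) {
    domains <- as.data.frame(domains)
    stopifnot(all(c("label", "start", "end") %in% names(domains)))
    if (any(domains$start < 1L | domains$end > L |
            domains$start > domains$end))
      stop("domain annotation outside [1, ", L, "]")
  }
  if (!is.null(contact_points)) {
    contact_points <- sort(as.integer(contact_points))
    if (anyDuplicated(contact_points))
      stop("contact points must be unique")
    local_max <- L - as.integer(numbering_offset)
    if (any(contact_points < 1L | contact_points > local_max))
      stop("contact points outside antigen-local range [1, ", local_max, "]")
  }
  structure(
    list(name = as.character(name), cds = cds, protein = protein,
         numbering_offset = as.integer(numbering_offset),
         domains = domains, contact_points = contact_points),
    class = "reference_antigen")
}

#' @export
print.reference_antigen <- function(x, ...) {
  cat("<reference_antigen> ", x$name, "\n", sep = "")
  cat("  cds: ", nchar(x$cds), " nt; protein: ", nchar(x$protein),
      " aa; numbering offset: ", x$numbering_offset, "\n", sep = "")
  if (!is.null(x$domains))
    cat("  domains: ", paste0(x$domains$label, " (", x$domains$start, "-",
                              x$domains$end, ")", collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$contact_points))
    cat("  contact points (antigen-local): ",
        length(x$contact_points), "\n", sep = "")
  invisible(x)
}

# position (codon index) of the first stop in a translated string, NA if none
stri_first_stop <- function(aa) {
  p <- stringi::stri_locate_first_fixed(aa, "*")[1, 1]
  p
}

#' Translate a coding sequence
#'
#' Standard genetic code translation via Biostrings.  Stop codons are
#' rendered as `*`.
#'
#' @param cds Character scalar of `ACGT` with length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Load a reference antigen from files
#'
#' Reads the coding sequence (FASTA), optionally a protein FASTA to
#' validate against, and an optional annotation TSV with columns
#' `type` (`domain` or `contact`), `label`, `start`, `end`.  Domain rows
#' are fusion residue spans; contact rows are antigen-local residues
#' (rows with `start < end` are expanded to the full range).
#'
#' @param cds_file Path to the CDS FASTA (first record used).
#' @param protein_file Optional protein FASTA path.
#' @param annotations Optional annotation TSV path.
#' @param numbering_offset Integer numbering offset (see
#'   [reference_antigen()]).
#' @param name Antigen name; defaults to the FASTA record name.
#' @return A `reference_antigen`.
#' @export
load_reference <- function(cds_file, protein_file = NULL,
                           annotations = NULL, numbering_offset = 0L,
                           name = NULL) {
  cds_set <- Biostrings::readDNAStringSet(cds_file)
  if (length(cds_set) < 1L) stop("no sequence in ", cds_file)
  cds <- as.character(cds_set[[1]])
  if (is.null(name)) name <- names(cds_set)[1]
  protein <- NULL
  if (!is.null(protein_file)) {
    aa_set <- Biostrings::readAAStringSet(protein_file)
    if (length(aa_set) < 1L) stop("no sequence in ", protein_file)
    protein <- as.character(aa_set[[1]])
  }
  domains <- NULL
  contacts <- NULL
  if (!is.null(annotations)) {
    ann <- read.delim(annotations, stringsAsFactors = FALSE)
    stopifnot(all(c("type", "label", "start", "end") %in% names(ann)))
    dom <- ann[ann$type == "domain", , drop = FALSE]
    if (nrow(dom)) domains <- dom[, c("label", "start", "end")]
    con <- ann[ann$type == "contact", , drop = FALSE]
    if (nrow(con))
      contacts <- unique(unlist(Map(seq.int, con$start, con$end)))
  }
  reference_antigen(name = name, cds = cds, protein = protein,
                    numbering_offset = numbering_offset,
                    domains = domains, contact_points = contacts)
}

#' Residue span
#'
#' A 1-based inclusive residue interval in one of two coordinate systems:
#' `"fusion"` (positions along the displayed fusion protein) or
#' `"antigen_local"` (the antigen's own numbering, e.g. the S140-K254
#' style labels used for fragment names).
#'
#' @param start,end Integer residue bounds, `1 <= start <= end`.
#' @param system `"fusion"` or `"antigen_local"`.
#' @return Object of class `residue_span`.
#' @export
residue_span <- function(start, end, system = c("fusion", "antigen_local")) {
  system <- match.arg(system)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid span: need 1 <= start <= end")
  structure(list(start = start, end = end, system = system),
            class = "residue_span")
}

#' @export
print.residue_span <- function(x, ...) {
  cat("<residue_span> ", x$start, "-", x$end, " [", x$system, "]\n",
      sep = "")
  invisible(x)
}

#' @export
format.residue_span <- function(x, ...)
  paste0(x$start, "-", x$end, " (", x$system, ")")

#' Convert a residue span between coordinate systems
#'
#' Fusion residue = antigen-local residue + `numbering_offset`.  The
#' conversion is a bijection on the covered region; a round trip returns
#' the original span.
#'
#' @param span A [residue_span()].
#' @param target Target system, `"fusion"` or `"antigen_local"`.
#' @param ref A [reference_antigen()] supplying the offset.
#' @return A `residue_span` in the target system.
#' @export
convert_span <- function(span, target = c("fusion", "antigen_local"), ref) {
  target <- match.arg(target)
  stopifnot(inherits(span, "residue_span"),
            inherits(ref, "reference_antigen"))
  if (span$system == target) return(span)
  off <- ref$numbering_offset
  L <- nchar(ref$protein)
  if (target == "fusion") {
    s <- span$start + off; e <- span$end + off
    if (s < 1L || e > L)
      stop("span ", format(span), " falls outside the fusion protein ",
           "after applying offset ", off)
  } else {
    s <- span$start - off; e <- span$end - off
    if (s < 1L || span$end > L)
      stop("span ", format(span), " falls outside the region covered by ",
           "the antigen-local numbering (offset ", off, ")")
  }
  residue_span(s, e, target)
}

#' Contact-point coverage of a span
#'
#' Counts how many annotated antigen-antibody contact residues fall
#' inside a residue span, e.g. to ask how much of a crystallographic
#' epitope an enriched fragment contains.
#'
#' @param span A [residue_span()] in either coordinate system.
#' @param ref A [reference_antigen()] with `contact_points` annotation.
#' @return Integer vector `c(covered, total)`.
#' @export
contact_coverage <- function(span, ref) {
  stopifnot(inherits(ref, "reference_antigen"))
  if (is.null(ref$contact_points))
    stop("contact-point annotation required: the reference has no ",
         "contact_points (supply an annotation file with contact rows)")
  loc <- convert_span(span, "antigen_local", ref)
  cp <- ref$contact_points
  c(covered = sum(cp >= loc$start & cp <= loc$end), total = length(cp))
}
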