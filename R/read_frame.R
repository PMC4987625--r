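#' @importFrom stringi stri_locate_first_fixed stri_sub stri_reverse
#'   stri_length stri_detect_regex
NULL

# reverse complement, vectorized, pure string ops (hot path)
revcomp <- function(x) stri_reverse(chartr("ACGTN", "TGCAN", x))

# Hamming distance between equal-length strings a and b (vectorized over
# pairs); NA-safe.  utf8ToInt is cheap for ASCII.
hamming_vec <- function(a, b) {
  mapply(function(x, y) {
    if (is.na(x) || is.na(y)) return(NA_integer_)
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# best approximate occurrence of `pat` in `read` by sliding Hamming
# search; returns c(start, mismatches) or c(NA, NA).  Ties broken by the
# leftmost occurrence.
best_hamming_match <- function(read, pat, max_mismatch) {
  n <- nchar(read); m <- nchar(pat)
  if (m == 0L || n < m) return(c(NA_integer_, NA_integer_))
  rr <- utf8ToInt(read); pr <- utf8ToInt(pat)
  k <- n - m + 1L
  mm <- integer(k)
  for (j in seq_len(m)) mm <- mm + (rr[j:(j + k - 1L)] != pr[j])
  best <- which.min(mm)
  if (mm[best] > max_mismatch) return(c(NA_integer_, NA_integer_))
  c(best, mm[best])
}

#' Extract phage inserts from raw reads
#'
#' Locates the two vector flank sequences in each read and returns the
#' subsequence strictly between them.  Exact flank matches are found
#' first (leftmost occurrence; the right flank is searched to the right
#' of the left one); reads whose flanks are not found exactly fall back
#' to a sliding-window Hamming search allowing up to `max_mismatch`
#' substitutions per flank.  An empty extracted insert denotes a
#' wild-type (empty-vector) clone.
#'
#' @param reads Character vector of read sequences (or a
#'   `DNAStringSet`).
#' @param flanks Character vector of length 2, `c(left, right)` flank
#'   sequences; see [default_flanks()].
#' @param max_mismatch Maximum substitutions tolerated per flank in the
#'   fallback search (default 1).
#' @param read_ids Optional read identifiers.
#' @return `data.frame` with columns `read_id`, `insert` (NA when a
#'   flank could not be located), `flank_mismatches`.
#' @export
extract_inserts <- function(reads, flanks = default_flanks(),
                            max_mismatch = 1L, read_ids = NULL) {
  if (inherits(reads, "XStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads), length(flanks) == 2L,
            all(nchar(flanks) > 0L))
  fl <- toupper(flanks[[1]]); fr <- toupper(flanks[[2]])
  n <- length(reads)
  if (n == 0L)
    return(data.frame(read_id = character(), insert = character(),
                      flank_mismatches = integer(),
                      stringsAsFactors = FALSE))
  if (is.null(read_ids))
    read_ids <- if (!is.null(names(reads)) && all(nzchar(names(reads))))
      names(reads) else paste0("read", seq_len(n))
  reads <- toupper(reads)

  locL <- stri_locate_first_fixed(reads, fl)
  endL <- locL[, 2]
  # right flank: leftmost occurrence after the left flank
  tails <- stri_sub(reads, ifelse(is.na(endL), 1L, endL + 1L))
  locR <- stri_locate_first_fixed(tails, fr)
  startR <- locR[, 1] + ifelse(is.na(endL), 0L, endL)
  fmm <- ifelse(is.na(endL) | is.na(locR[, 1]), NA_integer_, 0L)

  todo <- which(is.na(endL) | is.na(locR[, 1]))
  for (i in todo) {
    hl <- best_hamming_match(reads[i], fl, max_mismatch)
    if (is.na(hl[1])) next
    eL <- hl[1] + nchar(fl) - 1L
    tail_i <- substr(reads[i], eL + 1L, nchar(reads[i]))
    hr <- best_hamming_match(tail_i, fr, max_mismatch)
    if (is.na(hr[1])) next
    endL[i] <- eL
    startR[i] <- eL + hr[1]
    fmm[i] <- hl[2] + hr[2]
  }
  ok <- !is.na(endL) & !is.na(startR)
  insert <- rep(NA_character_, n)
  insert[ok] <- stri_sub(reads[ok], endL[ok] + 1L, startR[ok] - 1L)
  data.frame(read_id = read_ids, insert = insert,
             flank_mismatches = fmm, stringsAsFactors = FALSE)
}

# Vectorised placement of inserts on a single reference CDS.
# Returns list(start, mismatches) with NA where no acceptable placement.
# Strategy: exact substring first (stringi, leftmost), then seed-and-
# verify: up to three exact 20-mer seeds anchor a candidate offset which
# is verified by Hamming count against the reference segment.
place_on_cds <- function(inserts, cds, max_mismatch) {
  n <- length(inserts)
  start <- stri_locate_first_fixed(cds, inserts)[, 1]
  mism <- ifelse(is.na(start), NA_integer_, 0L)
  todo <- which(is.na(start))
  if (length(todo)) {
    ins <- inserts[todo]
    len <- stri_length(ins)
    L <- nchar(cds)
    seedlen <- 20L
    offs <- cbind(1L, pmax(1L, (len - seedlen) %/% 2L + 1L),
                  pmax(1L, len - seedlen + 1L))
    cand <- rep(NA_integer_, length(ins))
    for (k in 1:3) {
      need <- is.na(cand) & len >= seedlen
      if (!any(need)) break
      o <- offs[, k]
      seeds <- stri_sub(ins, o, o + seedlen - 1L)
      hit <- stri_locate_first_fixed(cds, seeds)[, 1]
      guess <- hit - o + 1L
      okg <- need & !is.na(guess) & guess >= 1L & guess + len - 1L <= L
      cand[okg] <- guess[okg]
    }
    ok <- which(!is.na(cand))
    if (length(ok)) {
      seg <- stri_sub(cds, cand[ok], cand[ok] + len[ok] - 1L)
      mm <- hamming_vec(ins[ok], seg)
      keep <- mm <= max_mismatch[todo][ok]
      start[todo[ok][keep]] <- cand[ok][keep]
      mism[todo[ok][keep]] <- mm[keep]
    }
  }
  list(start = start, mismatches = mism)
}

# first/last residue whose codon lies entirely within nt span [s, e]
res_span_from_nt <- function(s, e) {
  rs <- ceiling((s + 2L) / 3)
  re <- floor(e / 3)
  cbind(res_start = ifelse(rs <= re, as.integer(rs), NA_integer_),
        res_end   = ifelse(rs <= re, as.integer(re), NA_integer_))
}

#' Map inserts to the reference CDS and classify their cloning frame
#'
#' Each non-empty insert (or its reverse complement) is located on the
#' reference coding sequence; its 5' junction frame
#' `frame5 = (start - 1) mod 3`, length modulo 3, and orientation are
#' derived from the placement.  A clone is classified `natural` —
#' displaying the authentic antigen fragment fused to the capsid protein
#' — iff it is forward-oriented, in frame at the 5' junction
#' (`frame5 == 0`), has length divisible by 3, and contains no stop
#' codon in the displayed reading frame.  All other placed inserts are
#' `non_natural`; empty inserts are `empty`; inserts with no acceptable
#' placement are `unmapped`.  Under random cloning exactly 1 of the 18
#' equally likely (orientation x frame5 x length mod 3) configurations
#' is natural.
#'
#' @param inserts Character vector of insert sequences (`NA` = flank
#'   extraction failed; `""` = empty clone).
#' @param ref A [reference_antigen()].
#' @param min_match_len Minimum insert length considered mappable
#'   (default 12 nt).
#' @param max_mismatch_frac Maximum fraction of mismatching positions
#'   tolerated in the fallback placement (default 0.02).
#' @param read_ids Optional identifiers.
#' @return `data.frame` with columns `read_id`, `frame_class`,
#'   `orientation`, `nt_start`, `nt_end`, `res_start`, `res_end`,
#'   `frame5`, `len_mod3`, `mismatches`.
#' @export
map_inserts <- function(inserts, ref, min_match_len = 12L,
                        max_mismatch_frac = 0.02, read_ids = NULL) {
  stopifnot(inherits(ref, "reference_antigen"))
  n <- length(inserts)
  if (is.null(read_ids)) read_ids <- paste0("read", seq_len(n))
  out <- data.frame(
    read_id = read_ids,
    frame_class = rep("unmapped", n),
    orientation = rep(NA_character_, n),
    nt_start = rep(NA_integer_, n), nt_end = rep(NA_integer_, n),
    res_start = rep(NA_integer_, n), res_end = rep(NA_integer_, n),
    frame5 = rep(NA_integer_, n), len_mod3 = rep(NA_integer_, n),
    mismatches = rep(NA_integer_, n),
    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  inserts <- toupper(inserts)
  len <- stri_length(inserts)
  empty <- !is.na(inserts) & len == 0L
  out$frame_class[empty] <- "empty"
  cand <- which(!is.na(inserts) & len >= min_match_len)
  if (!length(cand)) return(out)

  cds <- ref$cds
  ins <- inserts[cand]
  maxmm <- as.integer(floor(max_mismatch_frac * len[cand]))
  fwd <- place_on_cds(ins, cds, maxmm)
  need_rc <- is.na(fwd$start)
  rc <- list(start = rep(NA_integer_, length(ins)),
             mismatches = rep(NA_integer_, length(ins)))
  if (any(need_rc)) {
    r <- place_on_cds(revcomp(ins[need_rc]), cds, maxmm[need_rc])
    rc$start[need_rc] <- r$start
    rc$mismatches[need_rc] <- r$mismatches
  }
  orient <- ifelse(!is.na(fwd$start), "forward",
                   ifelse(!is.na(rc$start), "reverse", NA_character_))
  start <- ifelse(orient == "forward", fwd$start, rc$start)
  mm <- ifelse(orient == "forward", fwd$mismatches, rc$mismatches)
  placed <- !is.na(orient)

  idx <- cand[placed]
  st <- start[placed]; ln <- len[cand][placed]
  out$orientation[idx] <- orient[placed]
  out$nt_start[idx] <- st
  out$nt_end[idx] <- st + ln - 1L
  out$frame5[idx] <- (st - 1L) %% 3L
  out$len_mod3[idx] <- ln %% 3L
  out$mismatches[idx] <- mm[placed]
  rs <- res_span_from_nt(st, st + ln - 1L)
  out$res_start[idx] <- rs[, 1]
  out$res_end[idx] <- rs[, 2]

  # natural-frame lottery plus the displayed-frame stop-codon screen
  lottery <- out$orientation[idx] == "forward" &
    out$frame5[idx] == 0L & out$len_mod3[idx] == 0L
  cls <- rep("non_natural", length(idx))
  if (any(lottery)) {
    seqs <- inserts[idx][lottery]
    cls[lottery][!has_internal_stop(seqs)] <- "natural"
  }
  out$frame_class[idx] <- cls
  out
}

# do in-frame inserts contain a stop codon in reading frame 0?
# (vectorized; batch-translated).  Non-ACGT inserts count as stops:
# their displayed peptide is undecodable.
has_internal_stop <- function(seqs) {
  out <- rep(TRUE, length(seqs))
  ok <- !stri_detect_regex(seqs, "[^ACGT]")
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(seqs[ok]), no.init.codon = TRUE))
    out[ok] <- stringi::stri_detect_fixed(aa, "*")
  }
  out
}

#' Classify a whole sequencing library
#'
#' Runs flank extraction (optionally) and frame classification over a
#' read set and summarises class counts.  `fraction_natural` is computed
#' among insert-bearing mapped reads, i.e. the denominator excludes
#' `empty` and `unmapped` reads.
#'
#' @param reads Character vector of raw reads (if `flanks` given) or of
#'   pre-extracted inserts (if `flanks = NULL`); a `DNAStringSet`; or a
#'   path to a FASTA/FASTQ file.
#' @param ref A [reference_antigen()].
#' @param flanks `c(left, right)` flank pair, or `NULL` when `reads` are
#'   already inserts.
#' @param max_mismatch_flank Per-flank substitution tolerance.
#' @param min_match_len,max_mismatch_frac Passed to [map_inserts()].
#' @return List of class `classification` with elements `fragments`
#'   (per-read `data.frame`) and `summary` (named list of counts and
#'   `fraction_natural`; `NA` when no insert-bearing read maps).
#' @export
classify_library <- function(reads, ref, flanks = default_flanks(),
                             max_mismatch_flank = 1L,
                             min_match_len = 12L,
                             max_mismatch_frac = 0.02) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  if (inherits(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(flanks)) {
    ext <- data.frame(
      read_id = if (!is.null(names(reads)) && all(nzchar(names(reads))))
        names(reads) else paste0("read", seq_along(reads)),
      insert = unname(reads), stringsAsFactors = FALSE)
  } else {
    ext <- extract_inserts(reads, flanks, max_mismatch = max_mismatch_flank)
  }
  frags <- map_inserts(ext$insert, ref, min_match_len = min_match_len,
                       max_mismatch_frac = max_mismatch_frac,
                       read_ids = ext$read_id)
  tab <- table(factor(frags$frame_class,
                      levels = c("empty", "natural", "non_natural",
                                 "unmapped")))
  denom <- tab[["natural"]] + tab[["non_natural"]]
  summary <- list(
    n_reads = nrow(frags),
    n_empty = tab[["empty"]],
    n_natural = tab[["natural"]],
    n_non_natural = tab[["non_natural"]],
    n_unmapped = tab[["unmapped"]],
    fraction_natural = if (denom > 0) tab[["natural"]] / denom else NA_real_)
  structure(list(fragments = frags, summary = summary),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  s <- x$summary
  cat("<classification> ", s$n_reads, " reads\n", sep = "")
  cat(sprintf("  empty: %d  natural: %d  non-natural: %d  unmapped: %d\n",
              s$n_empty, s$n_natural, s$n_non_natural, s$n_unmapped))
  cat("  natural-frame fraction (insert-bearing): ",
      if (is.na(s$fraction_natural)) "NA" else
        sprintf("%.4f", s$fraction_natural), "\n", sep = "")
  invisible(x)
}

#' Length statistics of natural-frame fragments
#'
#' Mean, median and sample standard deviation of the displayed fragment
#' lengths, in amino acids, over natural-frame clones only.
#'
#' @param fragments A `classification` or its `fragments` data frame.
#' @return Named numeric `c(mean, median, sd)` (sd is 0 for a single
#'   fragment).
#' @export
fragment_length_stats <- function(fragments) {
  if (inherits(fragments, "classification"))
    fragments <- fragments$fragments
  nat <- fragments[fragments$frame_class == "natural", , drop = FALSE]
  if (!nrow(nat))
    stop("no natural-frame fragments: length statistics undefined")
  len <- nat$res_end - nat$res_start + 1L
  c(mean = mean(len), median = median(len),
    sd = if (length(len) > 1L) sd(len) else 0)
}

#' Enumerate the 18 cloning-frame configurations of one fragment
#'
#' Constructs, from a fixed in-frame fragment of the reference CDS, all
#' 18 combinations of orientation (2), 5' junction frame (3) and length
#' modulo 3 (3), runs each through [map_inserts()], and returns the
#' classification table.  Under the random-cloning model exactly one
#' configuration — forward, in frame, length divisible by 3 — is
#' natural, which is the 1/18 (5.6%) display probability.
#'
#' @param ref A [reference_antigen()].
#' @param nt_start 1-based, in-frame start on the CDS
#'   (`(nt_start - 1) %% 3 == 0`).
#' @param nt_len Fragment length in nt, a multiple of 3, at least 15.
#' @return `data.frame` with columns `orientation`, `frame5`,
#'   `len_mod3`, `frame_class` (18 rows).
#' @export
enumerate_frame_classes <- function(ref, nt_start = 1L, nt_len = 90L) {
  stopifnot(inherits(ref, "reference_antigen"),
            (nt_start - 1L) %% 3L == 0L, nt_len %% 3L == 0L, nt_len >= 15L,
            nt_start + nt_len + 3L <= nchar(ref$cds))
  grid <- expand.grid(a = 0:2, b = 0:2,
                      orientation = c("forward", "reverse"),
                      stringsAsFactors = FALSE)
  ins <- stri_sub(ref$cds, nt_start + grid$a,
                  nt_start + nt_len - 1L - grid$b)
  ins[grid$orientation == "reverse"] <-
    revcomp(ins[grid$orientation == "reverse"])
  mapped <- map_inserts(ins, ref)
  data.frame(orientation = grid$orientation,
             frame5 = grid$a,
             len_mod3 = (nt_len - grid$a - grid$b) %% 3L,
             frame_class = mapped$frame_class,
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path File path; format inferred from the extension
#'   (`.fastq`/`.fq` vs FASTA), `.gz` allowed.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), names(x))
}
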