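# shared fixtures and independent oracles

tiny_ref <- function(n_res = 60L, offset = 0L, seed = 99L)
  synthetic_reference(n_res = n_res, numbering_offset = offset,
                      seed = seed, name = "tiny")

default_ref <- function() synthetic_reference(seed = 1L)

# brute-force translate-and-scan frame oracle, independent of the
# package's stringi-based mapping: scans all exact placements with
# Biostrings::matchPattern and checks the displayed reading frame.
oracle_frame_class <- function(insert, ref) {
  if (is.na(insert)) return("unmapped")
  if (nchar(insert) == 0L) return("empty")
  subj <- Biostrings::DNAString(ref$cds)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(insert), subj)
  if (length(fwd) > 0L) {
    s <- Biostrings::start(fwd)[1]
    if ((s - 1L) %% 3L == 0L && nchar(insert) %% 3L == 0L) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(insert), no.init.codon = TRUE))
      if (!grepl("*", aa, fixed = TRUE)) return("natural")
    }
    return("non_natural")
  }
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(insert)), subj)
  if (length(rev) > 0L) return("non_natural")
  "unmapped"
}

# naive sliding-window Hamming locator (nested loops) used as the
# flank-search oracle
oracle_best_match <- function(read, pat, max_mm) {
  n <- nchar(read); m <- nchar(pat)
  best_pos <- NA_integer_; best_mm <- max_mm + 1L
  if (n >= m) {
    rc <- strsplit(read, "")[[1]]
    pc <- strsplit(pat, "")[[1]]
    for (p in seq_len(n - m + 1L)) {
      mm <- sum(rc[p:(p + m - 1L)] != pc)
      if (mm < best_mm) { best_mm <- mm; best_pos <- p }
    }
  }
  if (is.na(best_pos) || best_mm > max_mm) return(NA_integer_)
  best_pos
}

# per-residue read tally by direct looping, used as the occurrence
# oracle
oracle_residue_tally <- function(frag, L) {
  sapply(seq_len(L), function(i)
    sum(frag$count[frag$res_start <= i & frag$res_end >= i]))
}

# construct a library_counts object directly from a span/count table
make_counts <- function(res_start, res_end, count,
                        library_id = "selected") {
  frag <- data.frame(res_start = as.integer(res_start),
                     res_end = as.integer(res_end),
                     count = as.integer(count))
  structure(list(library_id = library_id, fragments = frag,
                 total_natural_reads = sum(frag$count)),
            class = "library_counts")
}

# random in-frame / out-of-frame insert drawn from the simulator's
# cloning model (error-free)
random_insert <- function(ref) {
  L <- nchar(ref$cds)
  len <- sample(100:400, 1L)
  start <- sample(L - len + 1L, 1L)
  ins <- substr(ref$cds, start, start + len - 1L)
  if (runif(1) < 0.5)
    ins <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ins)))
  ins
}

run_sim_pair <- function(cfg) {
  lib <- simulate_library(cfg)
  sel <- simulate_selection(lib)
  list(lib = lib, sel = sel,
       cu = library_counts(
         classify_library(lib$reads$sequence, lib$cfg$ref), "unselected"),
       cs = library_counts(
         classify_library(sel$reads$sequence, lib$cfg$ref), "selected"))
}
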