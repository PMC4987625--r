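# run expr with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic reference antigen
#'
#' Builds a deterministic random fusion-protein reference of the kind
#' the simulator emulates: `n_res` sense codons drawn uniformly (no
#' internal stops), with an antigen-local numbering offset.  Defaults
#' mirror a 1314 bp / 438-residue carrier-antigen fusion whose C-terminal
#' 255 residues carry the antigen-local numbering.  The sequence is
#' synthetic: it is not any published antigen.
#'
#' @param n_res Number of residues (default 438).
#' @param numbering_offset Fusion-to-local numbering offset
#'   (default 183, so local residues run 1..255).
#' @param seed RNG seed for the codon draw (default 1; the caller's RNG
#'   stream is left untouched).
#' @param contact_points Optional antigen-local contact residues.
#' @param name Reference name.
#' @return A [reference_antigen()].
#' @export
synthetic_reference <- function(n_res = 438L, numbering_offset = 183L,
                                seed = 1L, contact_points = NULL,
                                name = "synthetic_fusion") {
  codons <- setdiff(all_kmers(c("A", "C", "G", "T"), 3L),
                    c("TAA", "TAG", "TGA"))
  cds <- with_seed(seed, paste0(
    sample(codons, n_res, replace = TRUE), collapse = ""))
  reference_antigen(name = name, cds = cds,
                    numbering_offset = numbering_offset,
                    contact_points = contact_points)
}

# all k-mers over an alphabet (small k)
all_kmers <- function(alphabet, k) {
  g <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

#' Simulation configuration
#'
#' Parameters of the random-fragment cloning and affinity-selection
#' simulator.  Defaults describe the emulated study design: DNase
#' shearing to 100-400 bp gel-purified fragments, blunt cloning in
#' random orientation and junction frame (the 1/18 natural-frame
#' lottery), a wild-type (empty-vector) clone fraction, two rounds of
#' antibody selection, and uniform substitution sequencing errors.
#'
#' @param ref A [reference_antigen()].
#' @param n_clones Library complexity (number of independent clones).
#' @param empty_fraction Fraction of wild-type (insert-free) clones.
#' @param fragment_length_range `c(min_bp, max_bp)` fragment sizes;
#'   must not exceed the gene length.
#' @param epitope_required_sets List of [residue_span()]s; a clone binds
#'   the antibody iff it is natural-frame and its displayed fragment
#'   covers every residue of every set (conjunctive coverage, no partial
#'   credit).
#' @param w_binder,w_background Multinomial selection weights for binder
#'   and non-binder clones (`w_binder >= w_background >= 0`).
#' @param n_rounds Number of selection rounds.
#' @param reads_per_round Sequencing reads drawn per library/round.
#' @param seq_error_rate Per-base substitution probability on emitted
#'   reads.
#' @param flanks Vector cloning-site flank pair added around each
#'   insert.
#' @param seed Optional integer seed; when set, a simulation run is
#'   bit-for-bit reproducible.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(ref, n_clones = 5000L, empty_fraction = 0.1,
                       fragment_length_range = c(100L, 400L),
                       epitope_required_sets = list(),
                       w_binder = 100, w_background = 1,
                       n_rounds = 2L, reads_per_round = 50000L,
                       seq_error_rate = 0.001,
                       flanks = default_flanks(), seed = NULL) {
  stopifnot(inherits(ref, "reference_antigen"))
  fragment_length_range <- as.integer(fragment_length_range)
  if (length(fragment_length_range) != 2L ||
      fragment_length_range[1] < 3L ||
      fragment_length_range[1] > fragment_length_range[2])
    stop("fragment_length_range must be c(min_bp, max_bp) with min >= 3")
  if (fragment_length_range[2] > nchar(ref$cds))
    stop("fragment_length_range exceeds the gene length (",
         nchar(ref$cds), " nt)")
  if (empty_fraction < 0 || empty_fraction > 1)
    stop("empty_fraction must be in [0, 1]")
  if (seq_error_rate < 0 || seq_error_rate > 1)
    stop("seq_error_rate must be in [0, 1]")
  if (!(w_binder >= w_background && w_background >= 0 && w_binder > 0))
    stop("need w_binder >= w_background >= 0 and w_binder > 0")
  sets <- lapply(epitope_required_sets, function(s) {
    stopifnot(inherits(s, "residue_span"))
    convert_span(s, "fusion", ref)
  })
  structure(list(ref = ref, n_clones = as.integer(n_clones),
                 empty_fraction = empty_fraction,
                 fragment_length_range = fragment_length_range,
                 epitope_required_sets = sets,
                 w_binder = w_binder, w_background = w_background,
                 n_rounds = as.integer(n_rounds),
                 reads_per_round = as.integer(reads_per_round),
                 seq_error_rate = seq_error_rate,
                 flanks = flanks, seed = seed),
            class = "sim_config")
}

# uniform substitution errors on a character vector of reads
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  nerr <- rbinom(length(seqs), len, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(len[i], nerr[i])
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    seqs[i] <- paste0(v, collapse = "")
  }
  seqs
}

# emit reads for a vector of clone indices
build_reads <- function(clones, idx, cfg, prefix) {
  ins <- clones$insert[idx]
  ins[is.na(ins)] <- ""
  reads <- paste0(cfg$flanks[[1]], ins, cfg$flanks[[2]])
  reads <- apply_seq_errors(reads, cfg$seq_error_rate)
  data.frame(read_id = paste0(prefix, seq_along(idx)),
             sequence = reads, clone_id = idx,
             stringsAsFactors = FALSE)
}

#' Simulate a random-fragment phage-display library
#'
#' Draws `n_clones` independent clones: with probability
#' `empty_fraction` a wild-type (no-insert) clone; otherwise a fragment
#' with length uniform in `fragment_length_range` and start uniform over
#' all positions where the fragment fits on the gene (the gel-purified
#' random-shearing model), cloned in random orientation.  The 5'
#' junction frame follows from the fragment start, so orientation,
#' junction frame and length modulo 3 form the 18-way cloning lottery
#' with natural-frame probability 1/18.  Unselected-library sequencing
#' is emulated by drawing `reads_per_round` reads uniformly from the
#' clone population, flanked by the vector sequences, with substitution
#' errors at `seq_error_rate`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_library`: list with `clones` (per-clone
#'   ground truth: span, orientation, `frame5`, `len_mod3`,
#'   `is_natural`, `is_binder`), `reads` (unselected sequencing run),
#'   `expected_natural_fraction` (1/18), and the `cfg`.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ref <- cfg$ref
  L <- nchar(ref$cds)
  n <- cfg$n_clones
  is_empty <- runif(n) < cfg$empty_fraction
  m <- sum(!is_empty)
  rng <- cfg$fragment_length_range
  len <- integer(n); len[] <- NA_integer_
  start <- integer(n); start[] <- NA_integer_
  orientation <- rep(NA_character_, n)
  if (m) {
    len[!is_empty] <- sample(seq.int(rng[1], rng[2]), m, replace = TRUE)
    start[!is_empty] <-
      1L + floor(runif(m) * (L - len[!is_empty] + 1L))
    orientation[!is_empty] <-
      sample(c("forward", "reverse"), m, replace = TRUE)
  }
  nt_end <- start + len - 1L
  frame5 <- (start - 1L) %% 3L
  len_mod3 <- len %% 3L
  insert <- rep(NA_character_, n)
  if (m) {
    insert[!is_empty] <-
      stringi::stri_sub(ref$cds, start[!is_empty], nt_end[!is_empty])
    rev <- which(orientation == "reverse")
    insert[rev] <- revcomp(insert[rev])
  }
  is_natural <- !is_empty & orientation == "forward" &
    frame5 == 0L & len_mod3 == 0L
  is_natural[is.na(is_natural)] <- FALSE
  rsp <- res_span_from_nt(start, nt_end)
  is_binder <- is_natural
  for (s in cfg$epitope_required_sets)
    is_binder <- is_binder & !is.na(rsp[, 1]) &
      rsp[, 1] <= s$start & rsp[, 2] >= s$end
  is_binder[is.na(is_binder)] <- FALSE
  clones <- data.frame(
    clone_id = seq_len(n), is_empty = is_empty,
    orientation = orientation, nt_start = start, nt_end = nt_end,
    res_start = rsp[, 1], res_end = rsp[, 2],
    frame5 = frame5, len_mod3 = len_mod3,
    is_natural = is_natural, is_binder = is_binder,
    insert = insert, stringsAsFactors = FALSE)
  idx <- sample.int(n, cfg$reads_per_round, replace = TRUE)
  reads <- build_reads(clones, idx, cfg, "u")
  structure(list(clones = clones, reads = reads,
                 expected_natural_fraction = 1 / 18, cfg = cfg),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library> ", nrow(x$clones), " clones (",
      sum(x$clones$is_empty), " empty, ",
      sum(x$clones$is_natural), " natural, ",
      sum(x$clones$is_binder), " binders); ",
      nrow(x$reads), " unselected reads\n", sep = "")
  invisible(x)
}

#' Simulate rounds of affinity selection
#'
#' Each round draws `reads_per_round` clones from a multinomial whose
#' weights are the previous round's clone abundances multiplied by
#' `w_binder` for binder clones and `w_background` otherwise (empty and
#' non-natural clones are background).  Round 1 samples the library
#' population at uniform abundance.  The final round is read out as a
#' sequencing run with the same read model as the unselected library.
#'
#' @param lib A [simulate_library()] result.
#' @param cfg Optional [sim_config()] override (defaults to
#'   `lib$cfg`).
#' @return Object of class `sim_selection`: list with `counts`
#'   (clone-by-round abundance matrix), `reads` (final-round sequencing
#'   run), `binder_fraction` (per round), and `cfg`.
#' @export
simulate_selection <- function(lib, cfg = NULL) {
  stopifnot(inherits(lib, "sim_library"))
  if (is.null(cfg)) cfg <- lib$cfg
  stopifnot(inherits(cfg, "sim_config"), cfg$n_rounds >= 1L)
  clones <- lib$clones
  w <- ifelse(clones$is_binder, cfg$w_binder, cfg$w_background)
  if (all(w == 0))
    stop("library contains no binders and w_background is 0: ",
         "selection would eliminate every clone")
  counts <- matrix(0L, nrow = nrow(clones), ncol = cfg$n_rounds)
  abundance <- rep(1, nrow(clones))
  for (r in seq_len(cfg$n_rounds)) {
    p <- abundance * w
    if (sum(p) == 0)
      stop("all surviving clones have zero selection weight in round ", r)
    counts[, r] <- as.integer(rmultinom(1L, cfg$reads_per_round, p))
    abundance <- counts[, r]
  }
  final <- counts[, cfg$n_rounds]
  idx <- sample(rep.int(seq_along(final), final))
  reads <- build_reads(clones, idx, cfg, "s")
  structure(list(counts = counts, reads = reads,
                 binder_fraction =
                   colSums(counts[clones$is_binder, , drop = FALSE]) /
                     cfg$reads_per_round,
                 cfg = cfg),
            class = "sim_selection")
}

#' @export
print.sim_selection <- function(x, ...) {
  cat("<sim_selection> ", ncol(x$counts), " round(s); binder fraction: ",
      paste(sprintf("%.3f", x$binder_fraction), collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

#' Write reads to FASTQ
#'
#' @param reads `data.frame` with `read_id` and `sequence` columns (as
#'   produced by the simulator), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads))
    reads <- setNames(reads$sequence, reads$read_id)
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      strrep("I", Biostrings::width(x))))
  invisible(path)
}
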