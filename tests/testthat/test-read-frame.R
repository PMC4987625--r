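test_that("inserts are extracted between flanks, including empty clones", {
  fl <- default_flanks()
  r1 <- paste0(fl[1], "ATGGCC", fl[2])
  r2 <- paste0(fl[1], fl[2])
  ext <- extract_inserts(c(r1, r2), fl)
  expect_equal(ext$insert, c("ATGGCC", ""))
  expect_equal(ext$flank_mismatches, c(0L, 0L))
})

test_that("flank search tolerates mismatches and agrees with a brute-force
           sliding-window oracle", {
  fl <- default_flanks()
  set.seed(21)
  ref <- tiny_ref()
  for (i in 1:40) {
    ins <- substr(ref$cds, 1, sample(30:120, 1))
    read <- paste0(fl[1], ins, fl[2])
    # mutate up to 1 position inside the left flank
    n_mut <- sample(0:1, 1)
    if (n_mut) {
      p <- sample(nchar(fl[1]), 1)
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(read, p, p)), 1)
    }
    got <- extract_inserts(read, fl, max_mismatch = 1)$insert
    pos <- oracle_best_match(read, fl[[1]], 1L)
    expect_false(is.na(pos))
    expect_equal(got, ins)
  }
  # two mismatches with max_mismatch = 1 -> unmapped
  bad <- paste0(fl[1], "AA", fl[2])
  substr(bad, 2, 3) <- "TG"
  expect_true(is.na(extract_inserts(bad, fl, max_mismatch = 1)$insert) ==
                is.na(oracle_best_match(bad, fl[[1]], 1L)))
})

test_that("in-frame forward inserts are natural; reverse never is", {
  ref <- tiny_ref()
  ins <- substr(ref$cds, 4, 63)          # frame5 = 0, len 60
  m <- map_inserts(ins, ref)
  expect_equal(m$frame_class, "natural")
  expect_equal(m$orientation, "forward")
  expect_equal(c(m$frame5, m$len_mod3), c(0L, 0L))
  expect_equal(c(m$res_start, m$res_end), c(2L, 21L))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ins)))
  expect_equal(map_inserts(rc, ref)$frame_class, "non_natural")
})

test_that("exactly one of the 18 cloning configurations is natural", {
  ref <- default_ref()
  e <- enumerate_frame_classes(ref, nt_start = 301, nt_len = 120)
  expect_equal(nrow(e), 18L)
  expect_equal(sum(e$frame_class == "natural"), 1L)
  nat <- e[e$frame_class == "natural", ]
  expect_equal(c(nat$orientation, nat$frame5, nat$len_mod3),
               c("forward", "0", "0"))
  expect_equal(1 / 18, 0.0556, tolerance = 1e-3)
})

test_that("a stop codon introduced into the displayed frame vetoes
           natural classification", {
  ref <- default_ref()
  ins <- substr(ref$cds, 301, 420)       # in-frame, 120 nt
  expect_equal(map_inserts(ins, ref)$frame_class, "natural")
  substr(ins, 61, 63) <- "TAA"           # internal stop, 1-3 mismatches
  m <- map_inserts(ins, ref, max_mismatch_frac = 0.05)
  expect_equal(m$frame_class, "non_natural")
  expect_equal(m$orientation, "forward")
  expect_equal(m$frame5, 0L)
})

test_that("mismatched inserts are still placed by the fallback search", {
  ref <- default_ref()
  set.seed(31)
  for (i in 1:20) {
    len <- sample(c(120, 240, 399), 1)
    s <- sample(nchar(ref$cds) - len + 1, 1)
    ins <- substr(ref$cds, s, s + len - 1)
    p <- sample(len, 2)
    for (q in p)
      substr(ins, q, q) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(ins, q, q)), 1)
    m <- map_inserts(ins, ref)
    expect_equal(m$nt_start, s)
    expect_lte(m$mismatches, 2L)
  }
})

test_that("library classification summarises counts and is
           permutation-invariant", {
  ref <- default_ref()
  cfg <- sim_config(ref, n_clones = 400, reads_per_round = 1200,
                    seq_error_rate = 0, seed = 17)
  lib <- simulate_library(cfg)
  cls <- classify_library(lib$reads$sequence, ref)
  s <- cls$summary
  expect_equal(s$n_reads, 1200L)
  expect_equal(s$n_empty + s$n_natural + s$n_non_natural + s$n_unmapped,
               1200L)
  expect_equal(s$fraction_natural,
               s$n_natural / (s$n_natural + s$n_non_natural))
  # classification against simulator truth (error-free reads)
  truth <- lib$clones$is_natural[lib$reads$clone_id]
  expect_equal(cls$fragments$frame_class == "natural", truth)
  # shuffling the stream changes no summary number
  set.seed(1)
  cls2 <- classify_library(sample(lib$reads$sequence), ref)
  expect_equal(cls2$summary, s)
  # degenerate inputs
  empty <- classify_library(character(0), ref)
  expect_equal(empty$summary$n_reads, 0L)
  expect_true(is.na(empty$summary$fraction_natural))
  fl <- default_flanks()
  wt_only <- classify_library(rep(paste0(fl[1], fl[2]), 5), ref)
  expect_true(is.na(wt_only$summary$fraction_natural))
  expect_equal(wt_only$summary$n_empty, 5L)
})

test_that("frame classification agrees with the translate-and-scan oracle", {
  ref <- default_ref()
  set.seed(41)
  inserts <- vapply(1:300, function(i) random_insert(ref), character(1))
  got <- map_inserts(inserts, ref)$frame_class
  want <- vapply(inserts, oracle_frame_class, character(1), ref = ref,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("fragment length statistics cover the stated examples", {
  frag <- data.frame(frame_class = "natural",
                     res_start = c(1, 1, 1), res_end = c(10, 20, 30))
  expect_equal(fragment_length_stats(frag),
               c(mean = 20, median = 20, sd = 10))
  one <- data.frame(frame_class = "natural", res_start = 1, res_end = 49)
  expect_equal(fragment_length_stats(one),
               c(mean = 49, median = 49, sd = 0))
  none <- data.frame(frame_class = "non_natural",
                     res_start = 1, res_end = 5)
  expect_error(fragment_length_stats(none), "no natural-frame")
})

test_that("natural fragment lengths match the cloning model expectation", {
  # uniform 100-400 bp fragments conditioned on frame -> mean ~ 250.5/3 aa
  ref <- default_ref()
  cfg <- sim_config(ref, n_clones = 10000, empty_fraction = 0,
                    reads_per_round = 100, seq_error_rate = 0, seed = 23)
  lib <- simulate_library(cfg)
  nat <- lib$clones[lib$clones$is_natural, ]
  len <- nat$res_end - nat$res_start + 1
  expect_equal(mean(len), 250.5 / 3, tolerance = 0.04)
})
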