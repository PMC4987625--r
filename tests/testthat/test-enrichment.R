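test_that("per-residue occurrence matches direct tallies", {
  ref <- tiny_ref(n_res = 20)
  # one fragment, all reads -> occurrence 1 on the span, 0 elsewhere
  c1 <- make_counts(1, 5, 4)
  occ <- residue_occurrence(c1, ref)
  expect_equal(occ, c(rep(1, 5), rep(0, 15)))
  # two disjoint fragments with equal counts -> 0.5 each
  c2 <- make_counts(c(1, 11), c(5, 15), c(6, 6))
  occ2 <- residue_occurrence(c2, ref)
  expect_equal(occ2[1:5], rep(0.5, 5))
  expect_equal(occ2[11:15], rep(0.5, 5))
  expect_equal(occ2[c(6:10, 16:20)], rep(0, 10))
  # random toy library agrees with the brute-force oracle
  set.seed(7)
  rs <- sample(15, 20, replace = TRUE)
  re <- pmin(20, rs + sample(0:5, 20, replace = TRUE))
  cr <- make_counts(rs, re, sample(1:9, 20, replace = TRUE))
  expect_equal(residue_occurrence(cr, ref) * cr$total_natural_reads,
               oracle_residue_tally(cr$fragments, 20))
  expect_error(residue_occurrence(make_counts(integer(), integer(),
                                              integer()), ref),
               "zero natural")
})

test_that("library_counts collapses natural reads and conserves them", {
  ref <- default_ref()
  cfg <- sim_config(ref, n_clones = 500, reads_per_round = 3000,
                    seq_error_rate = 0, seed = 9)
  lib <- simulate_library(cfg)
  cls <- classify_library(lib$reads$sequence, ref)
  lc <- library_counts(cls, "unselected")
  expect_equal(lc$total_natural_reads, cls$summary$n_natural)
  expect_true(all(lc$fragments$count >= 1L))
  expect_equal(sum(lc$fragments$count), lc$total_natural_reads)
})

test_that("enrichment factor follows the pseudocount formula", {
  ref <- tiny_ref(n_res = 20)
  # Csel = 20, Cunsel = 4, equal depths -> EF = 21/5 = 4.2
  sel <- make_counts(c(1, 6), c(5, 20), c(20, 80), "selected")
  uns <- make_counts(c(1, 6), c(5, 20), c(4, 96), "unselected")
  prof <- enrichment_factor(sel, uns, ref)
  expect_s3_class(prof, "residue_enrichment_profile")
  expect_equal(prof$ef[1:5], rep(21 / 5, 5))
  # identical libraries -> EF = 1 everywhere (covered or not)
  same <- enrichment_factor(sel, sel, ref)
  expect_equal(same$ef, rep(1, 20))
  expect_true(all(prof$ef > 0))
  expect_equal(nrow(prof), nchar(ref$protein))
})

test_that("uncovered residues sit at the depth-ratio baseline", {
  ref <- tiny_ref(n_res = 20)
  sel <- make_counts(1, 5, 30, "selected")     # Nsel = 30
  uns <- make_counts(1, 5, 10, "unselected")   # Nunsel = 10
  prof <- enrichment_factor(sel, uns, ref)
  expect_equal(prof$ef[6:20], rep(10 / 30, 15))
})

test_that("EF is scale-invariant in the zero-pseudocount limit", {
  ref <- tiny_ref(n_res = 20)
  # strictly positive tallies everywhere
  sel <- make_counts(c(1, 1, 10), c(20, 9, 20), c(5, 7, 11), "selected")
  uns <- make_counts(c(1, 8), c(20, 20), c(9, 4), "unselected")
  sel10 <- make_counts(c(1, 1, 10), c(20, 9, 20), 10 * c(5, 7, 11),
                       "selected")
  uns10 <- make_counts(c(1, 8), c(20, 20), 10 * c(9, 4), "unselected")
  p1 <- enrichment_factor(sel, uns, ref, pseudocount = 0)
  p2 <- enrichment_factor(sel10, uns10, ref, pseudocount = 0)
  expect_equal(p1$ef, p2$ef)
})

test_that("toy-library EF equals an independent hand computation", {
  ref <- tiny_ref(n_res = 25)
  set.seed(13)
  mk <- function(n, id) {
    rs <- sample(20, n, replace = TRUE)
    make_counts(rs, pmin(25, rs + sample(2:8, n, replace = TRUE)),
                sample(1:20, n, replace = TRUE), id)
  }
  sel <- mk(5, "selected"); uns <- mk(5, "unselected")
  prof <- enrichment_factor(sel, uns, ref)
  cs <- oracle_residue_tally(sel$fragments, 25)
  cu <- oracle_residue_tally(uns$fragments, 25)
  want <- ((cs + 1) / sel$total_natural_reads) /
    ((cu + 1) / uns$total_natural_reads)
  expect_equal(prof$ef, want)
  expect_equal(prof$occ_selected, cs / sel$total_natural_reads)
  expect_equal(prof$occ_unselected, cu / uns$total_natural_reads)
})

test_that("fragments rank by selected frequency with the span tie-break", {
  sel <- make_counts(c(3, 1, 8), c(12, 20, 10), c(50, 30, 20))
  rk <- rank_fragments(sel, top_n = 3)
  expect_equal(rk$frequency_selected, c(0.5, 0.3, 0.2))
  expect_equal(rk$res_start, c(3, 1, 8))
  # equal counts: longer span first, then smaller start
  tie <- make_counts(c(5, 1, 2), c(9, 10, 11), c(4, 4, 4))
  rk2 <- rank_fragments(tie, top_n = 3)
  expect_equal(rk2$res_start, c(1, 2, 5))
  # top_n beyond the table returns everything, with a message
  expect_message(rk3 <- rank_fragments(tie, top_n = 10), "returning all")
  expect_equal(nrow(rk3), 3L)
  # ranking loses no reads
  expect_equal(sum(rk3$count), tie$total_natural_reads)
})

test_that("mean + 5 SD significance rule handles the boundary cases", {
  # unselected frequencies all 0.01 (sd = 0); selected fragment at 0.02
  uns <- make_counts(seq(1, by = 2, length.out = 100),
                     seq(2, by = 2, length.out = 100),
                     rep(1, 100), "unselected")
  sel <- make_counts(c(1, 3), c(2, 4), c(2, 98), "selected")
  calls <- call_significant(sel, uns)
  expect_equal(attr(calls, "threshold"), 0.01)
  expect_true(all(calls$significant))   # 0.02 and 0.98 both exceed
  # selected identical to unselected -> nothing significant
  none <- call_significant(uns, uns)
  expect_false(any(none$significant))
  # sd undefined with a single unselected fragment
  expect_error(call_significant(sel, make_counts(1, 2, 5)),
               "fewer than 2 unique")
})
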