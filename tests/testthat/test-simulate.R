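test_that("simulation is deterministic under a fixed seed", {
  ref <- default_ref()
  cfg <- sim_config(ref, n_clones = 300, reads_per_round = 800, seed = 42)
  a <- simulate_library(cfg); sa <- simulate_selection(a)
  b <- simulate_library(cfg); sb <- simulate_selection(b)
  expect_identical(a$clones, b$clones)
  expect_identical(a$reads, b$reads)
  expect_identical(sa$counts, sb$counts)
  expect_identical(sa$reads, sb$reads)
  # byte-identical FASTQ
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(a$reads, f1); write_fastq(b$reads, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("config invariants are enforced", {
  ref <- tiny_ref(n_res = 60)   # 180 nt gene
  expect_error(sim_config(ref, fragment_length_range = c(100, 400)),
               "exceeds the gene length")
  expect_error(sim_config(ref, fragment_length_range = c(2, 50)),
               "min >= 3")
  expect_error(sim_config(ref, fragment_length_range = c(50, 100),
                          empty_fraction = 1.2), "empty_fraction")
  expect_error(sim_config(ref, fragment_length_range = c(50, 100),
                          w_binder = 1, w_background = 2), "w_binder")
})

test_that("empty_fraction = 1 emits only wild-type reads", {
  ref <- default_ref()
  cfg <- sim_config(ref, n_clones = 50, empty_fraction = 1,
                    reads_per_round = 100, seq_error_rate = 0, seed = 2)
  lib <- simulate_library(cfg)
  expect_true(all(lib$clones$is_empty))
  fl <- default_flanks()
  expect_true(all(lib$reads$sequence == paste0(fl[1], fl[2])))
})

test_that("selection conserves reads and enriches binders
           monotonically", {
  ref <- default_ref()
  sets <- list(residue_span(50, 60, "antigen_local"))
  cfg <- sim_config(ref, n_clones = 4000, reads_per_round = 5000,
                    epitope_required_sets = sets, n_rounds = 3,
                    w_binder = 100, w_background = 1,
                    seq_error_rate = 0, seed = 6)
  lib <- simulate_library(cfg)
  expect_gt(sum(lib$clones$is_binder), 0)
  # binder truth is conjunctive span coverage of every required set
  fus <- cfg$epitope_required_sets[[1]]
  covers <- !is.na(lib$clones$res_start) &
    lib$clones$res_start <= fus$start & lib$clones$res_end >= fus$end
  expect_identical(lib$clones$is_binder, lib$clones$is_natural & covers)
  sel <- simulate_selection(lib)
  expect_equal(unname(colSums(sel$counts)), rep(5000L, 3))
  expect_true(all(diff(sel$binder_fraction) > 0))
})

test_that("equal weights reduce selection to a plain resample", {
  ref <- default_ref()
  base <- list(n_clones = 500, reads_per_round = 2000,
               seq_error_rate = 0)
  cfg1 <- do.call(sim_config, c(list(ref), base,
                                list(w_binder = 1, w_background = 1,
                                     seed = 77)))
  cfg5 <- do.call(sim_config, c(list(ref), base,
                                list(w_binder = 5, w_background = 5,
                                     seed = 77)))
  s1 <- simulate_selection(simulate_library(cfg1))
  s5 <- simulate_selection(simulate_library(cfg5))
  # the weight scale cancels from the multinomial: identical draws
  expect_identical(s1$counts, s5$counts)
})

test_that("sequencing errors perturb reads at the configured rate", {
  ref <- default_ref()
  cfg0 <- sim_config(ref, n_clones = 200, reads_per_round = 400,
                     seq_error_rate = 0, seed = 3)
  cfg1 <- sim_config(ref, n_clones = 200, reads_per_round = 400,
                     seq_error_rate = 0.01, seed = 3)
  clean <- simulate_library(cfg0)$reads$sequence
  noisy <- simulate_library(cfg1)$reads$sequence
  mm <- mapply(function(a, b)
    if (nchar(a) == nchar(b))
      sum(utf8ToInt(a) != utf8ToInt(b)) else NA_integer_,
    clean, noisy)
  rate <- sum(mm, na.rm = TRUE) / sum(nchar(clean)[!is.na(mm)])
  expect_equal(rate, 0.01, tolerance = 0.3)
})

test_that("null selection strength flattens the EF profile", {
  # KS distance of EF to flatness decreases as w_binder/w_background -> 1
  ref <- default_ref()
  sets <- list(residue_span(50, 60, "antigen_local"))
  ks <- vapply(c(100, 5, 1), function(w) {
    cfg <- sim_config(ref, n_clones = 4000, reads_per_round = 8000,
                      epitope_required_sets = sets, w_binder = w,
                      seq_error_rate = 0, seed = 19)
    run <- run_sim_pair(cfg)
    prof <- enrichment_factor(run$cs, run$cu, ref)
    max(abs(log(prof$ef)))
  }, numeric(1))
  expect_true(ks[1] > ks[3])
  expect_true(ks[2] > ks[3] || ks[1] > ks[2])
})
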