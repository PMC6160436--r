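test_that("a fully modified always-stopping site truncates every read", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 200),
                    profiles = list(mod_profile("MT-TK", 40, f = 1, s = 1,
                                                m = 0)),
                    rng_seed = 11)
  lib <- simulate_library(cfg)
  expect_true(all(lib$truth$stop == "40"))
  # stop-before-copy: read covers 41..73, i.e. 33 nt
  expect_true(all(nchar(lib$reads) == 33L))
  tk_sense <- substr(tk_ref()$mature_seq, 41, 73)
  expect_true(all(revcomp(lib$reads) == tk_sense))
})

test_that("an unmodified error-free library is full-length mature sequence", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 50, "MT-TR" = 30), rng_seed = 3)
  lib <- simulate_library(cfg)
  expect_identical(sum(lib$truth$ref == "MT-TK"), 50L)
  expect_identical(sum(lib$truth$ref == "MT-TR"), 30L)
  expect_true(all(lib$truth$stop == "full"))
  sense <- revcomp(lib$reads)
  expect_true(all(sense[lib$truth$ref == "MT-TK"] == tk_ref()$mature_seq))
})

test_that("demethylase treatment erases stops at sensitive sites only", {
  rs <- fixture_refset()
  prof <- list(mod_profile("MT-TK", 40, f = 1, s = 1, m = 0,
                           demethylase_sensitive = TRUE),
               mod_profile("MT-TK", 34, f = 1, s = 0, m = 1,
                           demethylase_sensitive = FALSE))
  cfg <- sim_config(rs, c("MT-TK" = 100), profiles = prof,
                    demethylase_treated = TRUE, rng_seed = 5)
  lib <- simulate_library(cfg)
  expect_true(all(lib$truth$stop == "full"))           # methyl stop erased
  expect_true(all(grepl("^34:", lib$truth$mut_pos)))   # 2-thio signal kept
})

test_that("a fixed seed reproduces the FASTQ byte-for-byte", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 60, "MT-TR" = 40),
                    profiles = list(mod_profile("MT-TK", 54, 0.5, 0.45,
                                                0.45)),
                    cca_absent_fraction = 0.2, seq_error_rate = 0.01,
                    rng_seed = 7)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_library(cfg, fastq = f1)
  simulate_library(cfg, fastq = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("heteroplasmic variants appear at the configured fraction", {
  rs <- fixture_refset()
  n <- 4000L
  cfg <- sim_config(rs, c("MT-TK" = n),
                    heteroplasmy = data.frame(ref = "MT-TK",
                                              mature_index = 50,
                                              alt_base = "G",
                                              fraction = 0.8),
                    rng_seed = 13)
  lib <- simulate_library(cfg)
  frac <- mean(nzchar(lib$truth$variant))
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  expect_true(all(lib$truth$variant[nzchar(lib$truth$variant)] ==
                    "50:A>G"))
})

test_that("stopped plus full-length reads conserve the library size", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 500, "MT-TR" = 300),
                    profiles = list(
                      mod_profile("MT-TK", 40, 0.6, 0.5, 0.4),
                      mod_profile("MT-TK", 9, 0.9, 0.3, 0.5),
                      mod_profile("MT-TR", 16, 0.2, 0.45, 0.45)),
                    rng_seed = 21)
  lib <- simulate_library(cfg)
  for (nm in c("MT-TK", "MT-TR")) {
    tr <- lib$truth[lib$truth$ref == nm, ]
    per_pos_stops <- table(tr$stop[tr$stop != "full"])
    expect_identical(sum(per_pos_stops) + sum(tr$stop == "full"),
                     as.integer(cfg$reads_per_ref[[nm]]))
    # stops only at profiled positions
    expect_true(all(names(per_pos_stops) %in% c("40", "9", "16")))
  }
  # under s = 0 everywhere the length distribution collapses to full length
  cfg0 <- sim_config(rs, c("MT-TK" = 200),
                     profiles = list(mod_profile("MT-TK", 40, 0.8, 0,
                                                 0.9)),
                     rng_seed = 22)
  lib0 <- simulate_library(cfg0)
  expect_true(all(lib0$truth$stop == "full"))
  expect_true(all(nchar(lib0$reads) == nchar(tk_ref()$mature_seq)))
})

test_that("oligo(A) tails land only on the configured pool", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 800), cca_absent_fraction = 0.5,
                    oligoA = oligoA_spec(pool = "cca_absent",
                                         dist = "geometric", mean = 3),
                    rng_seed = 17)
  lib <- simulate_library(cfg)
  expect_true(all(lib$truth$tail_len[lib$truth$cca] == 0L))
  expect_gt(mean(lib$truth$tail_len[!lib$truth$cca]), 0)
  cfg2 <- sim_config(rs, c("MT-TK" = 50), cca_absent_fraction = 0,
                     oligoA = oligoA_spec(pool = "both", dist = "fixed",
                                          len = 4),
                     rng_seed = 18)
  lib2 <- simulate_library(cfg2)
  expect_true(all(lib2$truth$tail_len == 4L))
})

test_that("short cDNAs are dropped and resampled to an exact library size", {
  rs <- fixture_refset()
  # stop at index 64 leaves a 9-nt cDNA (< 15): always lost from the library
  cfg <- sim_config(rs, c("MT-TK" = 300),
                    profiles = list(mod_profile("MT-TK", 64, f = 0.5,
                                                s = 0.5, m = 0.9)),
                    min_insert_len = 15L, rng_seed = 9)
  lib <- simulate_library(cfg)
  expect_identical(nrow(lib$truth), 300L)
  expect_true(all(lib$truth$read_len >= 15L))
  expect_true(all(lib$truth$stop == "full"))
  expect_gt(lib$discarded[["MT-TK"]], 0L)
})

test_that("simulate_molecule shares the library generation path", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 10),
                    profiles = list(mod_profile("MT-TK", 40, 1, 1, 0)),
                    rng_seed = 2)
  set.seed(123)
  mol <- simulate_molecule(tk_ref(), cfg)
  expect_identical(mol$truth$stop, "40")
  expect_identical(mol$seq_read, revcomp(mol$seq_sense))
  expect_error(simulate_molecule(
    trna_reference("ZZZ", strrep("ACGT", 15)), cfg), "not in")
})
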