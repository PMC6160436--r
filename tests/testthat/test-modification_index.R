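test_that("the Modification Index is the shared-denominator sum", {
  expect_equal(modification_index(0.086, 0.074), 0.16)
  expect_identical(modification_index(0, 0), 0)
  expect_error(modification_index(0.7, 0.4), "denominator")
  expect_error(modification_index(-0.1, 0.2), "\\[0, 1\\]")
  expect_true(is.na(modification_index(NA_real_, NA_real_)))
})

test_that("position counts match a hand count on a constructed pileup", {
  ref <- trna_reference("HC1", strrep("ACGT", 15))  # mature length 63
  rs <- reference_set(list(ref))
  p <- 30L
  # 2 reads stop at p (start p+1); 8 read through; 1 read-through mismatched
  rec <- data.frame(
    read_id = sprintf("h%02d", 1:10), ref_name = "HC1", variant = "mature",
    start = c(rep(p + 1L, 2L), rep(1L, 8L)), end = 63L,
    n_mismatch = c(rep(0L, 9L), 1L),
    mismatches = c(rep("", 9L), paste0(p, ":G>A")),
    orientation = "antisense", unique = TRUE, pass = "primary",
    soft_tail = "", seq = "x", read_len = 63L, stringsAsFactors = FALSE)
  tab <- build_position_table(rec, rs, min_coverage = 5)
  row <- tab[tab$pos == p, ]
  expect_identical(row$N, 10L)
  expect_identical(row$S, 2L)
  expect_identical(row$R, 8L)
  expect_identical(row$X, 1L)
  expect_equal(row$stop_frac, 0.2)
  expect_equal(row$mut_frac, 0.1)
  expect_equal(row$MI, 0.3)
  # all-full-length, mismatch-free pileup gives MI 0 everywhere covered
  rec0 <- rec
  rec0$start <- 1L; rec0$n_mismatch <- 0L; rec0$mismatches <- ""
  tab0 <- build_position_table(rec0, rs, min_coverage = 5)
  expect_true(all(tab0$MI[tab0$ref == "HC1"] == 0))
  # S + R = N at every interior position
  expect_true(all(tab$S + tab$R == tab$N))
})

test_that("simulated MI recovers f*(s + (1-s)*m) away from the 3' end", {
  rs <- fixture_refset()
  f <- 0.6; s <- 0.3; m <- 0.5
  n <- 20000L
  cfg <- sim_config(rs, c("MT-TK" = n),
                    profiles = list(mod_profile("MT-TK", 40, f, s, m)),
                    rng_seed = 41)
  lib <- simulate_library(cfg)
  aln <- align_reads(length_filter(lib$reads), rs)
  tab <- build_position_table(aln, rs)
  mi <- tab$MI[tab$ref == "MT-TK" & tab$pos == 40]
  expected <- f * (s + (1 - s) * m)   # 0.39
  expect_lt(abs(mi - expected),
            4 * sqrt(expected * (1 - expected) / n))
  # conservation on the simulated library: stops + full length = aligned
  tk <- tab[tab$ref == "MT-TK", ]
  expect_identical(sum(tk$S) + attr(tab, "full_length")[["MT-TK"]],
                   attr(tab, "aligned_unique")[["MT-TK"]])
})

test_that("3'-proximal lower-bound positions are flagged as configured", {
  rs <- fixture_refset()
  rec <- data.frame(read_id = "r1", ref_name = "MT-TK", variant = "mature",
                    start = 1L, end = 73L, n_mismatch = 0L, mismatches = "",
                    orientation = "antisense", unique = TRUE,
                    pass = "primary", soft_tail = "", seq = "x",
                    read_len = 73L, stringsAsFactors = FALSE)
  tab <- build_position_table(rec, rs, min_coverage = 1)
  tk <- tab[tab$ref == "MT-TK", ]
  expect_true(tk$lower_bound[tk$pos == 54])    # 19 nt from the 3' end
  expect_false(tk$lower_bound[tk$pos == 33])   # 40 nt away
  relaxed <- flag_lower_bound(tab, threshold = 0)
  expect_false(any(relaxed$lower_bound))
})

test_that("treated/untreated differential separates methyl from 2-thio", {
  rs <- fixture_refset()
  prof <- list(mod_profile("MT-TK", 40, f = 0.9, s = 0.45, m = 0.45,
                           demethylase_sensitive = TRUE),
               mod_profile("MT-TK", 34, f = 0.9, s = 0, m = 0.25,
                           demethylase_sensitive = FALSE))
  n <- 8000L
  mk <- function(treated, seed) {
    cfg <- sim_config(rs, c("MT-TK" = n), profiles = prof,
                      seq_error_rate = 0.001,
                      demethylase_treated = treated, rng_seed = seed)
    lib <- simulate_library(cfg)
    build_position_table(align_reads(length_filter(lib$reads), rs), rs)
  }
  tab_u <- mk(FALSE, 51)
  tab_t <- mk(TRUE, 52)
  calls <- call_modifications(tab_u, tab_t)
  call_at <- function(p) calls$call[calls$ref == "MT-TK" & calls$pos == p]
  expect_identical(call_at(40L), "demethylase_sensitive_methyl")
  expect_identical(call_at(34L), "non_methyl_signal")
  expect_identical(call_at(20L), "unmodified")
  # demethylase erasure: treated MI at the methyl site is error-level
  mi_t <- tab_t$MI[tab_t$ref == "MT-TK" & tab_t$pos == 40]
  expect_lte(mi_t, 3 * 0.001)
  # conventional numbering travels with the call
  expect_identical(calls$conv_pos[calls$ref == "MT-TK" & calls$pos == 54],
                   58L)
})

test_that("a template methyl leaves a mutation peak at p, read ends at p+1", {
  rs <- fixture_refset()
  q <- 9L  # m1A9-like D-arm site
  cfg <- sim_config(rs, c("MT-TK" = 6000),
                    profiles = list(mod_profile("MT-TK", q, f = 0.9,
                                                s = 0.5, m = 0.5)),
                    rng_seed = 61)
  lib <- simulate_library(cfg)
  aln <- align_reads(length_filter(lib$reads), rs)
  rec <- aln$records[aln$records$ref_name == "MT-TK" & aln$records$unique, ]
  five_prime_ends <- table(rec$start[rec$start > 1])
  peak_end <- as.integer(names(which.max(five_prime_ends)))
  tab <- build_position_table(aln, rs)
  tk <- tab[tab$ref == "MT-TK", ]
  peak_mut <- tk$pos[which.max(tk$X)]
  expect_identical(peak_mut, q)           # misincorporation at the site
  expect_identical(peak_end, q + 1L)      # truncated reads begin one 3' of it
})

test_that("modified-fraction estimation scales a mutation-only MI", {
  expect_equal(estimate_modified_fraction(0.24, 0.5), 0.48)
  expect_equal(estimate_modified_fraction(0.3, 1), 0.3)
  # empirical context-matched share instead of equal contributions
  expect_equal(estimate_modified_fraction(0.24, 0.074 / 0.16), 0.519,
               tolerance = 1e-3)
  expect_error(estimate_modified_fraction(0.2, 0), "\\(0, 1\\]")
  expect_warning(est <- estimate_modified_fraction(0.8, 0.5), "capping")
  expect_identical(est, 1)
})
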