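test_that("length filtering removes sub-15-nt fragments at the boundary", {
  reads <- setNames(c(strrep("A", 14), strrep("C", 15), strrep("G", 40)),
                    c("a", "b", "c"))
  kept <- length_filter(reads)
  expect_identical(names(kept), c("b", "c"))
  expect_identical(attr(kept, "n_removed"), 1L)
  empty <- length_filter(setNames(character(0), character(0)))
  expect_length(empty, 0L)
})

test_that("adapter trimming is exact-suffix with a minimum overlap", {
  adapter <- "AGATCGGAAGAGCACACGTC"
  body <- "ACGTTGCATGCATTGACCTA"
  reads <- setNames(c(paste0(body, adapter),
                      paste0(body, substr(adapter, 1, 3)),
                      adapter,
                      paste0(body, "AAAAAAAA")),
                    c("full", "short_ov", "pure", "tail"))
  out <- trim_adapter(reads, adapter)
  expect_identical(unname(out["full"]), body)
  # 3-base overlap is below the minimum: untouched
  expect_identical(unname(out["short_ov"]), paste0(body, "AGA"))
  expect_identical(unname(out["pure"]), "")
  expect_length(length_filter(out), 3L)  # pure-adapter read then drops out
  # homopolymer tails are preserved, never quality-clipped
  expect_identical(unname(out["tail"]), paste0(body, "AAAAAAAA"))
})

test_that("unique, tied, and over-threshold reads follow the -v/-m policy", {
  rs <- mini_refset()
  m1 <- rs$references$TST1$mature_seq
  exact <- setNames(revcomp(substr(m1, 5, 34)), "u1")
  aln <- align_reads(exact, rs)
  expect_identical(nrow(aln$records), 1L)
  expect_identical(aln$records$ref_name, "TST1")
  expect_identical(aln$records$start, 5L)
  expect_identical(aln$records$n_mismatch, 0L)
  expect_true(aln$records$unique)
  expect_identical(aln$records$orientation, "antisense")

  # a 20-mer shared verbatim by two references: two tied records
  shared <- "ACGTACGTTTGGCCAATCGA"
  g <- function(stem) paste0(shared, stem)
  rs2 <- reference_set(list(
    trna_reference("SH1", g(paste0(strrep("C", 20), strrep("G", 20)))),
    trna_reference("SH2", g(paste0(strrep("T", 20), strrep("G", 20))))))
  aln2 <- align_reads(setNames(shared, "s1"), rs2)
  expect_identical(nrow(aln2$records), 2L)
  expect_false(any(aln2$records$unique))
  expect_setequal(aln2$records$ref_name, c("SH1", "SH2"))

  # best placement with 4 mismatches: unaligned under -v 3
  chars <- strsplit(substr(m1, 5, 34), "")[[1]]
  for (p in c(2, 9, 16, 23)) chars[p] <- setdiff(c("A", "C", "G", "T"),
                                                 chars[p])[1]
  bad <- setNames(paste(chars, collapse = ""), "m4")
  aln3 <- align_reads(bad, rs)
  expect_identical(nrow(aln3$records), 0L)
  expect_identical(aln3$unaligned, "m4")
})

test_that("poly-A remapping recovers tailed reads with soft tails", {
  rs <- mini_refset()
  r1 <- rs$references$TST1
  m1 <- r1$mature_seq
  L <- nchar(m1)
  tailed <- setNames(revcomp(paste0(substr(m1, L - 24, L), "AAAAAA")),
                     "t1")
  aln <- align_reads(tailed, rs)
  rec <- aln$records
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$pass, "polyA_remap")
  expect_identical(rec$variant, "mature_polyA")
  expect_identical(nchar(rec$soft_tail), 6L)
  expect_identical(rec$end, L)

  # CCA-less adenylated molecule needs the gene+poly-A reference variant
  gene_tail <- setNames(revcomp(paste0(substr(r1$gene_seq, 36, 60),
                                       "AAAAA")), "t2")
  aln2 <- align_reads(gene_tail, rs)
  expect_identical(aln2$records$variant, "gene_polyA")
  expect_identical(aln2$records$n_mismatch, 0L)
  expect_identical(nchar(aln2$records$soft_tail), 5L)

  # an untailed unalignable read stays unaligned after the remap pass
  noise <- setNames(paste(rep(c("A", "C", "G", "T"), 10), collapse = ""),
                    "n1")
  aln3 <- align_reads(noise, rs)
  expect_identical(aln3$unaligned, "n1")
})

test_that("the scanning aligner matches a brute-force enumerator exactly", {
  rs <- reference_set(fixture_refset()$references[1:5], polyA_n = 30L)
  reads <- random_reads(rs, 200L, seed = 101)
  aln <- align_reads(reads, rs)
  panel_primary <- dmtrnaseq:::primary_panel(rs)
  panel_polyA <- dmtrnaseq:::polyA_panel(rs)
  for (id in names(reads)) {
    o1 <- oracle_align_one(reads[[id]], panel_primary)
    expected <- if (o1$status == "unaligned") {
      oracle_align_one(reads[[id]], panel_polyA)
    } else o1
    got <- aln$records[aln$records$read_id == id, , drop = FALSE]
    if (expected$status == "aligned") {
      keyify <- function(ref, variant, off, ori) {
        paste(ref, variant, off, ori, sep = "/")
      }
      exp_keys <- sort(vapply(expected$hits, function(h)
        keyify(h$ref, h$variant, h$offset, h$ori), character(1)))
      got_keys <- sort(keyify(got$ref_name, got$variant, got$start,
                              ifelse(got$orientation == "antisense",
                                     "rc", "fwd")))
      expect_identical(got_keys, exp_keys)
      expect_true(all(got$n_mismatch == expected$nmm))
      expect_identical(unique(got$unique), length(expected$hits) == 1L)
    } else if (expected$status == "suppressed") {
      expect_identical(nrow(got), 0L)
      expect_true(id %in% aln$suppressed)
    } else {
      expect_identical(nrow(got), 0L)
      expect_true(id %in% aln$unaligned)
    }
  }
  # no record ever exceeds the mismatch ceiling; order is deterministic
  expect_true(all(aln$records$n_mismatch <= 3L))
  expect_identical(aln$records$read_id, sort(aln$records$read_id))
})

test_that("SAM output round-trips through the reader", {
  rs <- fixture_refset()
  cfg <- sim_config(rs, c("MT-TK" = 120, "MT-TR" = 80),
                    profiles = list(mod_profile("MT-TK", 40, 0.6, 0.5,
                                                0.8)),
                    cca_absent_fraction = 0.3, seq_error_rate = 0.005,
                    rng_seed = 31)
  lib <- simulate_library(cfg)
  aln <- align_reads(length_filter(lib$reads), rs)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, rs, sam, reads = lib$reads)
  lines <- readLines(sam)
  expect_identical(sum(startsWith(lines, "@SQ")), 22L)
  back <- read_sam(sam)
  cols <- c("read_id", "ref_name", "variant", "start", "end",
            "mismatches", "orientation", "unique", "pass", "soft_tail",
            "seq")
  a <- aln$records[order(aln$records$read_id, aln$records$ref_name,
                         aln$records$start), cols]
  b <- back$records[order(back$records$read_id, back$records$ref_name,
                          back$records$start), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  expect_identical(sort(back$unaligned), sort(aln$unaligned))
  # antisense placements carry FLAG 16 and the reference-forward sequence
  body <- lines[!startsWith(lines, "@")]
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  expect_true(any(bitwAnd(flags, 16L) == 16L))
  # standard tooling parses the file, when available
  if (nzchar(Sys.which("samtools"))) {
    n_mapped <- as.integer(system2("samtools",
                                   c("view", "-c", "-F", "4", sam),
                                   stdout = TRUE))
    expect_identical(n_mapped, nrow(aln$records))
  }
})
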