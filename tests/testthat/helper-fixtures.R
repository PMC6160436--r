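# Shared fixtures: the packaged 22-reference synthetic mitochondrial tRNA
# set, small hand-built references, and an independent brute-force aligner
# used as the oracle for the scanning aligner.

fixture_refset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_references(
        system.file("extdata", "mt_trna_synthetic.fa", package = "dmtrnaseq"),
        system.file("extdata", "mt_trna_synthetic_meta.tsv",
                    package = "dmtrnaseq"))
    }
    cache
  }
})

tk_ref <- function() fixture_refset()$references[["MT-TK"]]

# two fixed 60-nt gene bodies for hand-checkable alignment tests
mini_refset <- function() {
  g1 <- paste0("ATGCGTACGTTAGCCTAGGATCCGATTACGGCTAAGTCGA",
               "CCTGATCGGAAGTCATCGTG")
  g2 <- paste0("TTACGGATCAGCCGGATTTACGCTAGCATGCAAGGTTCAG",
               "GACTTGACCTAGGCATTAAC")
  reference_set(list(trna_reference("TST1", g1),
                     trna_reference("TST2", g2)), polyA_n = 30L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Plain-R brute-force enumerator over all offsets and both orientations:
# computes every placement's Hamming distance with character vectors, then
# applies the best-stratum / max-hits policy. Independent of the C++ path.
oracle_align_one <- function(read, panel, max_mismatch = 3L,
                             max_hits = 10L) {
  hits <- list()
  best <- max_mismatch + 1L
  for (ori in c("fwd", "rc")) {
    rd <- if (ori == "rc") revcomp(read) else read
    rchars <- strsplit(rd, "")[[1]]
    L <- length(rchars)
    for (j in seq_len(nrow(panel))) {
      refchars <- strsplit(panel$seq[j], "")[[1]]
      RL <- length(refchars)
      if (L > RL) next
      for (o in seq_len(RL - L + 1L)) {
        d <- sum(rchars != refchars[o:(o + L - 1L)])
        if (d <= max_mismatch && d <= best) {
          if (d < best) {
            best <- d
            hits <- list()
          }
          hits[[length(hits) + 1L]] <-
            list(ref = panel$ref_name[j], variant = panel$variant[j],
                 offset = o, ori = ori, nmm = d)
        }
      }
    }
  }
  if (!length(hits)) return(list(status = "unaligned"))
  if (length(hits) > max_hits) {
    return(list(status = "suppressed", n = length(hits), nmm = best))
  }
  list(status = "aligned", hits = hits, nmm = best)
}

# random reads derived from a reference set: exact, mutated, truncated,
# tailed, or pure noise; returned in cDNA orientation like real input
random_reads <- function(refset, n, seed) {
  set.seed(seed)
  refs <- refset$references
  reads <- character(n)
  for (i in seq_len(n)) {
    type <- sample(c("exact", "mut", "trunc", "tail", "noise"), 1L,
                   prob = c(0.3, 0.3, 0.2, 0.15, 0.05))
    ref <- refs[[sample(length(refs), 1L)]]
    m <- ref$mature_seq
    L <- nchar(m)
    start <- sample(seq_len(L - 20L), 1L)
    s <- substr(m, start, L)
    chars <- strsplit(s, "")[[1]]
    if (type %in% c("mut", "tail")) {
      k <- sample(0:4, 1L)
      if (k > 0) {
        pos <- sample(length(chars), min(k, length(chars)))
        for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  chars[p]), 1L)
      }
    }
    if (type == "trunc") chars <- chars[seq_len(max(15L, length(chars) - 5L))]
    if (type == "tail") chars <- c(chars, rep("A", sample(1:8, 1L)))
    if (type == "noise") chars <- sample(c("A", "C", "G", "T"), 40L,
                                         replace = TRUE)
    reads[i] <- revcomp(paste(chars, collapse = ""))
  }
  setNames(reads, sprintf("rr%04d", seq_len(n)))
}

# fixed, deterministic relative abundances for the 22-reference fixture
fixture_abundances <- function(refset) {
  n <- length(refset$references)
  setNames(exp(seq(log(0.2), log(3), length.out = n)),
           names(refset$references))
}
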