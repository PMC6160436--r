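#' Classify the 3' end of each uniquely aligned read
#'
#' Sorts reads into CCA-present and CCA-absent pools and measures any 3'
#' oligo(A) extension. A read is classifiable only if it reaches the gene
#' 3' end (internal RT stops say nothing about CCA status and are excluded,
#' not counted as CCA-absent). CCA presence requires the read to cover all
#' three CCA positions with an exact, mismatch-free "CCA": a single
#' mismatch there is indistinguishable from absence at this depth, so a
#' read ending "..CC" is never CCA-present. The tail is everything beyond
#' the templated end -- beyond the CCA for CCA-present reads, beyond the
#' gene body otherwise (so adenosines replacing an absent CCA count as
#' tail) -- and `oligoA_len` is the maximal terminal adenosine run within
#' it; mixed tails are kept verbatim in `tail_seq`.
#'
#' @param x A `trna_alignment`, records data.frame, or SAM path.
#' @param refset The `trna_reference_set`.
#' @param min_tail Minimum terminal A-run length to call a read adenylated
#'   (default 1).
#' @return A data.frame of tail records (read_id, ref_name, cca_present,
#'   body_end, tail_seq, oligoA_len, is_adenylated) with attribute
#'   `n_excluded` (unique reads not reaching the 3' region).
#' @export
classify_tails <- function(x, refset, min_tail = 1L) {
  stopifnot(inherits(refset, "trna_reference_set"))
  rec <- alignment_records(x)
  rec <- rec[rec$unique, , drop = FALSE]
  glen <- vapply(refset$references, gene_length, integer(1))
  L <- vapply(refset$references, mature_length, integer(1))
  g <- glen[rec$ref_name]
  Lr <- L[rec$ref_name]
  reaches <- rec$end >= g
  out <- rec[reaches, , drop = FALSE]
  g <- g[reaches]
  Lr <- Lr[reaches]
  n <- nrow(out)
  cca <- logical(n)
  tail_seq <- character(n)
  for (k in seq_len(n)) {
    r <- out[k, ]
    covers_cca <- r$end >= Lr[k] && r$start <= g[k] + 1L
    cca_bases <- if (covers_cca) {
      substr(r$seq, g[k] + 1L - r$start + 1L, Lr[k] - r$start + 1L)
    } else ""
    cca[k] <- covers_cca && identical(cca_bases, "CCA")
    templated_end <- if (cca[k]) Lr[k] else g[k]
    read_body_chars <- templated_end - r$start + 1L
    tail_seq[k] <- substr(r$seq, read_body_chars + 1L, nchar(r$seq))
  }
  oligoA <- nchar(tail_seq) - nchar(sub("A*$", "", tail_seq))
  res <- data.frame(read_id = out$read_id, ref_name = out$ref_name,
                    cca_present = cca, body_end = pmin(out$end, g),
                    tail_seq = tail_seq, oligoA_len = oligoA,
                    is_adenylated = oligoA >= min_tail,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!reaches)
  res
}

#' Oligo(A) tail-length distribution per tRNA and CCA pool
#'
#' The per-reference frequency of adenylation: within each (reference,
#' pool) cell, the fraction of reads with each terminal A-run length.
#' Fractions within a cell sum to 1. Pools smaller than `min_pool` are
#' flagged low-confidence.
#'
#' @param tail_records Output of [classify_tails()].
#' @param min_pool Minimum pool size for a confident distribution
#'   (default 20).
#' @return A data.frame with columns ref, pool ("CCA"/"noCCA"), len, n,
#'   fraction, pool_n, low_confidence.
#' @export
adenylation_frequency <- function(tail_records, min_pool = 20L) {
  pool <- ifelse(tail_records$cca_present, "CCA", "noCCA")
  key <- paste(tail_records$ref_name, pool, sep = "\r")
  out <- lapply(split(seq_len(nrow(tail_records)), key), function(idx) {
    lens <- tail_records$oligoA_len[idx]
    tab <- table(lens)
    data.frame(ref = tail_records$ref_name[idx[1]], pool = pool[idx[1]],
               len = as.integer(names(tab)), n = as.integer(tab),
               fraction = as.integer(tab) / length(idx),
               pool_n = length(idx),
               low_confidence = length(idx) < min_pool,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(ref = character(0), pool = character(0),
                      len = integer(0), n = integer(0),
                      fraction = numeric(0), pool_n = integer(0),
                      low_confidence = logical(0))
  }
  res <- res[order(res$ref, res$pool, res$len), , drop = FALSE]
  rownames(res) <- NULL
  res
}
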