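#' Remove reads below the minimum alignable length
#'
#' Fragments shorter than 15 nt are too short to place reliably on the
#' compact tRNA references and are removed before alignment.
#'
#' @param reads Named character vector of read sequences.
#' @param min_len Minimum read length kept (default 15).
#' @return The surviving reads, with attribute `n_removed`.
#' @export
length_filter <- function(reads, min_len = 15L) {
  keep <- nchar(reads) >= min_len
  out <- reads[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trim a 3' sequencing-adapter trace from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, requiring at least `min_overlap` bases. Purely sequence-based:
#' no quality trimming, so low-complexity homonucleotide stretches (real
#' oligo(A) tails) are preserved for the 3'-tail analysis.
#'
#' @param reads Named character vector.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum suffix/prefix overlap to trim (default 5).
#' @return Trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nzchar(adapter))
  alen <- nchar(adapter)
  vapply(reads, function(r) {
    rlen <- nchar(r)
    for (k in seq.int(min(rlen, alen), 1L)) {
      if (k < min_overlap) break
      if (substr(r, rlen - k + 1L, rlen) == substr(adapter, 1L, k)) {
        return(substr(r, 1L, rlen - k))
      }
    }
    r
  }, character(1))
}

# Reference panels handed to the C++ scanner. body_limit is the largest
# reference coordinate that is templated tRNA (mature or gene body);
# anything aligned beyond it sits in the appended poly-A tract.
primary_panel <- function(refset) {
  refs <- refset$references
  data.frame(ref_name = names(refs), variant = "mature",
             seq = vapply(refs, `[[`, character(1), "mature_seq"),
             body_limit = vapply(refs, mature_length, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

polyA_panel <- function(refset) {
  refs <- refset$references
  n <- refset$polyA_n
  rbind(
    data.frame(ref_name = names(refs), variant = "mature_polyA",
               seq = vapply(refs, build_polyA_reference, character(1), n = n),
               body_limit = vapply(refs, mature_length, integer(1)),
               stringsAsFactors = FALSE, row.names = NULL),
    # gene body + poly-A, no CCA: lets adenylated CCA-lacking molecules
    # align end-to-end instead of fighting the templated CCA.
    data.frame(ref_name = names(refs), variant = "gene_polyA",
               seq = vapply(refs, function(r)
                 paste0(r$gene_seq, strrep("A", n)), character(1)),
               body_limit = vapply(refs, gene_length, integer(1)),
               stringsAsFactors = FALSE, row.names = NULL))
}

empty_records <- function() {
  data.frame(read_id = character(0), ref_name = character(0),
             variant = character(0), start = integer(0), end = integer(0),
             n_mismatch = integer(0), mismatches = character(0),
             orientation = character(0), unique = logical(0),
             pass = character(0), soft_tail = character(0),
             seq = character(0), read_len = integer(0),
             stringsAsFactors = FALSE)
}

scan_panel <- function(reads, panel, max_mismatch, max_hits, pass) {
  if (!length(reads)) {
    return(list(records = empty_records(), status = integer(0)))
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(reads))))
  hit <- scan_align(unname(reads), rc, panel$seq, max_mismatch, max_hits)
  if (!length(hit$read)) {
    return(list(records = empty_records(), status = hit$status))
  }
  i <- hit$read
  j <- hit$ref
  len <- nchar(reads)[i]
  oriented <- ifelse(hit$is_rc == 1L, rc[i], unname(reads)[i])
  ref_start <- hit$offset + 1L
  ref_end <- hit$offset + len
  limit <- panel$body_limit[j]
  start <- pmin(ref_start, limit + 1L)
  end <- pmin(ref_end, limit)
  keep <- start <= end          # drop tract-only placements (no tRNA body)
  tail_n <- pmax(ref_end - limit, 0L)
  soft_tail <- ifelse(tail_n > 0L,
                      substr(oriented, len - tail_n + 1L, len), "")
  rec <- data.frame(
    read_id = names(reads)[i], ref_name = panel$ref_name[j],
    variant = panel$variant[j], start = start, end = end,
    n_mismatch = hit$nmm, mismatches = "",
    orientation = ifelse(hit$is_rc == 1L, "antisense", "sense"),
    unique = hit$stratum_size[i] == 1L, pass = pass,
    soft_tail = soft_tail, seq = oriented, read_len = len,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # mismatch triples (mature coordinates), body positions only
  need <- which(rec$n_mismatch > 0L)
  if (length(need)) {
    jj <- j[keep]
    rs <- ref_start[keep]
    for (k in need) {
      a <- charToRaw(rec$seq[k])
      b <- charToRaw(substr(panel$seq[jj[k]], rs[k],
                            rs[k] + rec$read_len[k] - 1L))
      d <- which(a != b)
      pos <- rs[k] + d - 1L
      in_body <- pos <= panel$body_limit[jj[k]]
      if (any(in_body)) {
        rec$mismatches[k] <- paste0(
          pos[in_body], ":", strsplit(rawToChar(b[d[in_body]]), "")[[1]],
          ">", strsplit(rawToChar(a[d[in_body]]), "")[[1]], collapse = ";")
      }
    }
  }
  list(records = rec, status = hit$status)
}

#' Align reads to the tRNA reference set
#'
#' Ungapped end-to-end placement of every read at every offset of every
#' reference, both orientations (Bowtie-1 `-v`-mode semantics): placements
#' with at most `max_mismatch` mismatches are found, only the
#' minimum-mismatch stratum is kept, and a read whose best stratum exceeds
#' `max_hits` placements is suppressed (defaults mirror
#' `-v 3 -m 10 --best --strata`). Reads the primary pass cannot place are
#' remapped against poly-A-appended references (mature + A-tract, and gene
#' body + A-tract for CCA-lacking adenylated molecules); tract-aligned
#' 3' bases are reported as `soft_tail`.
#'
#' @param reads Named character vector (pass through [length_filter()]
#'   first).
#' @param refset A `trna_reference_set`.
#' @param max_mismatch Maximum mismatches per placement (default 3).
#' @param max_hits Maximum best-stratum size before suppression (default 10).
#' @param polyA_pass Run the poly-A remapping pass on primary-unaligned
#'   reads (default TRUE).
#' @return A `trna_alignment` list: `records` (one row per placement;
#'   multi-mapped reads appear once per tied placement with
#'   `unique = FALSE`), `summary` (read accounting), `unaligned` and
#'   `suppressed` read ids. Coordinates are 1-based mature-sequence
#'   positions of the templated body; `seq` is the read oriented to the
#'   reference forward strand.
#' @export
align_reads <- function(reads, refset, max_mismatch = 3L, max_hits = 10L,
                        polyA_pass = TRUE) {
  stopifnot(inherits(refset, "trna_reference_set"))
  if (is.null(names(reads)) || anyDuplicated(names(reads))) {
    stop("reads must carry unique names")
  }
  reads <- toupper(reads)
  p1 <- scan_panel(reads, primary_panel(refset), max_mismatch, max_hits,
                   "primary")
  suppressed <- names(reads)[p1$status == 2L]
  unaligned1 <- names(reads)[p1$status == 0L]
  rec <- p1$records
  if (polyA_pass && length(unaligned1)) {
    p2 <- scan_panel(reads[unaligned1], polyA_panel(refset), max_mismatch,
                     max_hits, "polyA_remap")
    suppressed <- c(suppressed, unaligned1[p2$status == 2L])
    unaligned <- unaligned1[p2$status == 0L]
    rec <- rbind(rec, p2$records)
  } else {
    unaligned <- unaligned1
  }
  rec <- rec[order(rec$read_id, rec$ref_name, rec$start), , drop = FALSE]
  rownames(rec) <- NULL
  aligned_ids <- unique(rec$read_id)
  summary <- data.frame(
    total = length(reads), aligned = length(aligned_ids),
    unique = sum(rec$unique), multimapped = length(unique(
      rec$read_id[!rec$unique])),
    suppressed = length(suppressed), unaligned = length(unaligned),
    polyA_remapped = length(unique(rec$read_id[rec$pass == "polyA_remap"])))
  structure(list(records = rec, summary = summary, unaligned = unaligned,
                 suppressed = suppressed),
            class = "trna_alignment")
}

#' @export
print.trna_alignment <- function(x, ...) {
  cat("<trna_alignment>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Remap unaligned reads against poly-A-appended references
#'
#' The standalone poly-A remapping pass used by [align_reads()]: the same
#' best-stratum policy against mature + poly-A and gene-body + poly-A
#' references, with tract-aligned bases reported as `soft_tail`.
#'
#' @inheritParams align_reads
#' @return A `trna_alignment` list (records carry `pass = "polyA_remap"`).
#' @export
polyA_remap <- function(reads, refset, max_mismatch = 3L, max_hits = 10L) {
  stopifnot(inherits(refset, "trna_reference_set"))
  reads <- toupper(reads)
  p <- scan_panel(reads, polyA_panel(refset), max_mismatch, max_hits,
                  "polyA_remap")
  rec <- p$records[order(p$records$read_id, p$records$ref_name,
                         p$records$start), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 summary = data.frame(
                   total = length(reads), aligned = length(unique(rec$read_id)),
                   unique = sum(rec$unique),
                   multimapped = length(unique(rec$read_id[!rec$unique])),
                   suppressed = sum(p$status == 2L),
                   unaligned = sum(p$status == 0L),
                   polyA_remapped = length(unique(rec$read_id))),
                 unaligned = names(reads)[p$status == 0L],
                 suppressed = names(reads)[p$status == 2L]),
            class = "trna_alignment")
}
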