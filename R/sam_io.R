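# Mismatch strings ("54:A>G;60:C>T") <-> parsed triples.
parse_mismatches <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "[:>]")
  data.frame(pos = as.integer(vapply(parts, `[`, character(1), 1L)),
             ref = vapply(parts, `[`, character(1), 2L),
             alt = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

# MD tag for an ungapped M-block starting at `start` with length `mlen`,
# given body-mismatch positions/ref bases (mature coordinates).
build_md <- function(start, mlen, mm) {
  if (!nrow(mm)) return(as.character(mlen))
  mm <- mm[order(mm$pos), , drop = FALSE]
  out <- character(0)
  prev <- start - 1L
  for (k in seq_len(nrow(mm))) {
    out <- c(out, as.character(mm$pos[k] - prev - 1L), mm$ref[k])
    prev <- mm$pos[k]
  }
  paste0(paste(out, collapse = ""), start + mlen - 1L - prev)
}

parse_md <- function(md, start, seq) {
  toks <- regmatches(md, gregexpr("[0-9]+|[A-Z^]+", md))[[1]]
  pos <- start
  out <- list()
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      pos <- pos + as.integer(t)
    } else {
      for (b in strsplit(t, "")[[1]]) {
        out[[length(out) + 1L]] <-
          data.frame(pos = pos, ref = b,
                     alt = substr(seq, pos - start + 1L, pos - start + 1L),
                     stringsAsFactors = FALSE)
        pos <- pos + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write alignments as SAM
#'
#' Standard SAM 1.6 with one `@SQ` line per mature reference. Mapped rows
#' carry the templated body as the M block (POS in mature coordinates) and
#' any poly-A-tract-aligned tail as a 3' soft clip; mismatches are encoded
#' in `NM`/`MD` over the M block. `MAPQ` 255 marks unique placements, 0
#' multi-mapped ties. Antisense placements get FLAG 16 with `SEQ` stored
#' reference-forward. Unaligned and suppressed reads appear as FLAG 4
#' records tagged `XS:Z:unaligned` / `XS:Z:suppressed`. Extra tags:
#' `XP:Z:` pass, `XV:Z:` reference variant matched.
#'
#' @param aln A `trna_alignment` from [align_reads()].
#' @param refset The `trna_reference_set` aligned against.
#' @param path Output path.
#' @param reads Optional named read vector so unaligned/suppressed reads
#'   can be emitted with their sequence.
#' @return The path, invisibly.
#' @export
write_sam <- function(aln, refset, path, reads = NULL) {
  stopifnot(inherits(aln, "trna_alignment"),
            inherits(refset, "trna_reference_set"))
  refs <- refset$references
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(refs, function(r)
             sprintf("@SQ\tSN:%s\tLN:%d", r$name, mature_length(r)),
             character(1)),
           sprintf("@PG\tID:dmtrnaseq\tPN:dmtrnaseq\tVN:%s",
                   as.character(packageVersion("dmtrnaseq"))))
  rec <- aln$records
  body_lines <- character(0)
  if (nrow(rec)) {
    body_lines <- vapply(seq_len(nrow(rec)), function(k) {
      r <- rec[k, ]
      mm <- parse_mismatches(r$mismatches)
      mlen <- r$end - r$start + 1L
      slen <- nchar(r$soft_tail)
      cigar <- paste0(mlen, "M", if (slen > 0L) paste0(slen, "S") else "")
      paste(r$read_id, if (r$orientation == "antisense") 16L else 0L,
            r$ref_name, r$start, if (r$unique) 255L else 0L, cigar,
            "*", 0L, 0L, r$seq, "*",
            paste0("NM:i:", nrow(mm)),
            paste0("MD:Z:", build_md(r$start, mlen, mm)),
            paste0("XP:Z:", r$pass), paste0("XV:Z:", r$variant),
            sep = "\t")
    }, character(1))
  }
  un <- character(0)
  emit_unmapped <- function(ids, why) {
    vapply(ids, function(id) {
      sq <- if (!is.null(reads) && id %in% names(reads)) reads[[id]] else "*"
      paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, sq, "*",
            paste0("XS:Z:", why), sep = "\t")
    }, character(1))
  }
  un <- c(emit_unmapped(aln$unaligned, "unaligned"),
          emit_unmapped(aln$suppressed, "suppressed"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body_lines, un), con, sep = "\n")
  invisible(path)
}

#' Read a dmtrnaseq SAM file back into alignment records
#'
#' Parses the ungapped single-M-block (plus optional 3' soft clip) SAM
#' dialect written by [write_sam()], reconstructing mismatch triples from
#' `MD` and the soft tail from the CIGAR.
#'
#' @param path SAM path.
#' @return A `trna_alignment` list.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  unaligned <- character(0)
  suppressed <- character(0)
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L) {
      why <- sub("^XS:Z:", "", grep("^XS:Z:", f, value = TRUE)[1])
      if (identical(why, "suppressed")) {
        suppressed <- c(suppressed, f[1])
      } else {
        unaligned <- c(unaligned, f[1])
      }
      next
    }
    cig <- regmatches(f[6], gregexpr("[0-9]+[MS]", f[6]))[[1]]
    mlen <- as.integer(sub("M", "", cig[grepl("M", cig)][1]))
    slen <- if (any(grepl("S", cig))) {
      as.integer(sub("S", "", cig[grepl("S", cig)][1]))
    } else 0L
    start <- as.integer(f[4])
    seq <- f[10]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f, value = TRUE)[1])
    mm <- parse_md(md, start, seq)
    pass <- sub("^XP:Z:", "", grep("^XP:Z:", f, value = TRUE)[1])
    variant <- sub("^XV:Z:", "", grep("^XV:Z:", f, value = TRUE)[1])
    rows[[k]] <- data.frame(
      read_id = f[1], ref_name = f[3],
      variant = if (is.na(variant)) "mature" else variant,
      start = start, end = start + mlen - 1L, n_mismatch = nrow(mm),
      mismatches = if (nrow(mm))
        paste0(mm$pos, ":", mm$ref, ">", mm$alt, collapse = ";") else "",
      orientation = if (bitwAnd(flag, 16L) == 16L) "antisense" else "sense",
      unique = as.integer(f[5]) == 255L,
      pass = if (is.na(pass)) "primary" else pass,
      soft_tail = if (slen > 0L) substr(seq, nchar(seq) - slen + 1L,
                                        nchar(seq)) else "",
      seq = seq, read_len = nchar(seq), stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rec)) rec <- empty_records()
  rownames(rec) <- NULL
  structure(list(records = rec,
                 summary = data.frame(
                   total = length(unique(c(rec$read_id, unaligned,
                                           suppressed))),
                   aligned = length(unique(rec$read_id)),
                   unique = sum(rec$unique),
                   multimapped = length(unique(rec$read_id[!rec$unique])),
                   suppressed = length(suppressed),
                   unaligned = length(unaligned),
                   polyA_remapped = length(unique(
                     rec$read_id[rec$pass == "polyA_remap"]))),
                 unaligned = unaligned, suppressed = suppressed),
            class = "trna_alignment")
}
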