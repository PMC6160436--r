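#' Construct a single tRNA reference
#'
#' A reference couples the genomic tRNA gene body (no CCA) with the mature
#' sequence (gene + the post-transcriptionally added 3' CCA), strand and
#' genomic metadata, and a map from conventional tRNA numbering to mature
#' sequence coordinates. Mitochondrial tRNAs lack classical D/T arms, so
#' conventional positions (e.g. 58 in the T loop) need not equal the
#' sequence index; the map is therefore supplied data, never derived.
#'
#' All downstream coordinates in the package are 1-based, inclusive, on the
#' mature (CCA-appended) sequence, 5' to 3' in tRNA sense.
#'
#' @param name Reference identifier, e.g. `"MT-TK"`.
#' @param gene_seq Gene-body DNA string (A/C/G/T/N), 5' to 3', without CCA.
#' @param strand Coding-strand label, `"H"` or `"L"`.
#' @param genome_start Optional 1-based genomic coordinate of the gene 5'
#'   end; carried for labeling only (e.g. m.8348), never used for alignment.
#' @param numbering_map Named integer vector: names are conventional tRNA
#'   positions, values are 1-based mature-sequence indices.
#'
#' @return An object of class `trna_reference`.
#' @export
trna_reference <- function(name, gene_seq, strand = "H",
                           genome_start = NA_integer_,
                           numbering_map = integer()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  gene_seq <- toupper(as.character(gene_seq))
  if (grepl("[^ACGTN]", gene_seq)) {
    stop("reference '", name, "' contains characters outside A/C/G/T/N")
  }
  glen <- nchar(gene_seq)
  if (glen < 55L || glen > 100L) {
    stop("reference '", name, "' gene length ", glen,
         " outside the plausible tRNA range [55, 100]")
  }
  if (!strand %in% c("H", "L")) stop("strand must be 'H' or 'L'")
  numbering_map <- setNames(as.integer(numbering_map), names(numbering_map))
  if (length(numbering_map)) {
    if (is.null(names(numbering_map)) || any(!nzchar(names(numbering_map)))) {
      stop("numbering_map must be a named vector (conventional -> index)")
    }
    if (anyDuplicated(numbering_map)) {
      stop("numbering_map values must be unique for '", name, "'")
    }
    if (any(numbering_map < 1L | numbering_map > glen)) {
      stop("numbering_map indices out of gene range for '", name, "'")
    }
  }
  structure(
    list(name = name, gene_seq = gene_seq,
         mature_seq = paste0(gene_seq, "CCA"), strand = strand,
         genome_start = as.integer(genome_start),
         numbering_map = numbering_map),
    class = "trna_reference")
}

#' @export
print.trna_reference <- function(x, ...) {
  cat(sprintf("<trna_reference> %s  strand %s  gene %d nt, mature %d nt\n",
              x$name, x$strand, nchar(x$gene_seq), nchar(x$mature_seq)))
  if (length(x$numbering_map)) {
    cat("  numbering:", paste0(names(x$numbering_map), "->",
                               x$numbering_map, collapse = " "), "\n")
  }
  invisible(x)
}

gene_length <- function(ref) nchar(ref$gene_seq)
mature_length <- function(ref) nchar(ref$mature_seq)

#' Bundle tRNA references into a reference set
#'
#' @param references List of [trna_reference()] objects.
#' @param polyA_n Length of the adenosine tract appended when building
#'   remapping references for 3'-tailed reads (default 30).
#'
#' @return An object of class `trna_reference_set`: a list with elements
#'   `references` (named list) and `polyA_n`.
#' @export
reference_set <- function(references, polyA_n = 30L) {
  stopifnot(is.list(references), length(references) >= 1L)
  ok <- vapply(references, inherits, logical(1), "trna_reference")
  if (!all(ok)) stop("all elements must be trna_reference objects")
  nm <- vapply(references, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate reference names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  polyA_n <- as.integer(polyA_n)
  if (is.na(polyA_n) || polyA_n < 1L) stop("polyA_n must be >= 1")
  names(references) <- nm
  structure(list(references = references, polyA_n = polyA_n),
            class = "trna_reference_set")
}

#' @export
print.trna_reference_set <- function(x, ...) {
  cat(sprintf("<trna_reference_set> %d references, polyA_n = %d\n",
              length(x$references), x$polyA_n))
  print(reference_summary(x), row.names = FALSE)
  invisible(x)
}

#' Summarise a reference set
#'
#' One row per reference: name, strand, gene and mature lengths, genomic
#' start and the number of conventional-numbering entries. This is the
#' table behind reference validation.
#'
#' @param refset A `trna_reference_set`.
#' @return A data.frame.
#' @export
reference_summary <- function(refset) {
  stopifnot(inherits(refset, "trna_reference_set"))
  do.call(rbind, lapply(refset$references, function(r) {
    data.frame(name = r$name, strand = r$strand,
               gene_len = gene_length(r), mature_len = mature_length(r),
               genome_start = r$genome_start,
               n_numbering = length(r$numbering_map),
               stringsAsFactors = FALSE)
  }))
}

#' Load a tRNA reference set from FASTA plus metadata
#'
#' FASTA records hold the gene bodies (no CCA; it is appended here to form
#' the mature sequences). The metadata TSV has columns `name`, `strand`,
#' `genome_start` and `numbering` (semicolon-separated `conv:idx` pairs);
#' references absent from the metadata default to strand "H" and an empty
#' numbering map.
#'
#' @param fasta_path Path to the gene-body FASTA.
#' @param metadata_path Optional path to the metadata TSV.
#' @param polyA_n Poly-A tract length for remapping references.
#'
#' @return A `trna_reference_set`.
#' @export
load_references <- function(fasta_path, metadata_path = NULL, polyA_n = 30L) {
  # read permissively so that invalid alphabets are reported per record
  seqs <- Biostrings::readBStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate reference names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
    need <- c("name", "strand", "genome_start", "numbering")
    miss <- setdiff(need, names(meta))
    if (length(miss)) stop("metadata missing columns: ",
                           paste(miss, collapse = ", "))
  }
  refs <- lapply(seq_along(seqs), function(i) {
    strand <- "H"; gstart <- NA_integer_; nmap <- integer()
    if (!is.null(meta) && nm[i] %in% meta$name) {
      row <- meta[match(nm[i], meta$name), ]
      if (!is.na(row$strand) && nzchar(row$strand)) strand <- row$strand
      gstart <- suppressWarnings(as.integer(row$genome_start))
      nmap <- parse_numbering(row$numbering)
    }
    trna_reference(nm[i], as.character(seqs[[i]]), strand = strand,
                   genome_start = gstart, numbering_map = nmap)
  })
  reference_set(refs, polyA_n = polyA_n)
}

# "58:54;9:9;34:34" -> c(`58` = 54L, `9` = 9L, `34` = 34L)
parse_numbering <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(integer())
  pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(pairs, length, integer(1)) != 2L
  if (any(bad)) stop("malformed numbering entry: ", x)
  setNames(as.integer(vapply(pairs, `[`, character(1), 2L)),
           vapply(pairs, `[`, character(1), 1L))
}

#' Append a poly-A tract to a mature reference
#'
#' Remapping references for 3'-tailed reads: the mature sequence followed by
#' `n` adenosines, so oligoadenylated molecules align end-to-end.
#'
#' @param ref A `trna_reference`.
#' @param n Tract length (>= 1).
#' @return A DNA string of length `nchar(mature_seq) + n`.
#' @export
build_polyA_reference <- function(ref, n = 30L) {
  stopifnot(inherits(ref, "trna_reference"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("poly-A tract length must be >= 1")
  paste0(ref$mature_seq, strrep("A", n))
}

#' Resolve a conventional tRNA position to a mature-sequence index
#'
#' @param ref A `trna_reference`.
#' @param conventional_pos Conventional tRNA position (e.g. 58).
#' @return The 1-based mature-sequence index.
#' @export
resolve_position <- function(ref, conventional_pos) {
  stopifnot(inherits(ref, "trna_reference"))
  key <- as.character(conventional_pos)
  if (!key %in% names(ref$numbering_map)) {
    stop("conventional position ", key, " not mapped for '", ref$name,
         "'; available: ",
         if (length(ref$numbering_map))
           paste(names(ref$numbering_map), collapse = ", ")
         else "(none)")
  }
  unname(ref$numbering_map[[key]])
}

#' Distance from a mature-sequence position to the 3' end
#'
#' The count of nucleotides strictly 3' of the position on the mature
#' sequence. Because all DM-tRNA-seq reads start from the 3' CCA, an RT stop
#' at a position closer than the minimum insert length produces a cDNA too
#' short for the library, so stop fractions are only trusted for positions
#' more than ~25 nt from the 3' end.
#'
#' @param ref A `trna_reference`.
#' @param mature_index 1-based mature-sequence index.
#' @return Integer distance (0 for the 3'-terminal base).
#' @export
distance_to_3prime <- function(ref, mature_index) {
  stopifnot(inherits(ref, "trna_reference"))
  mature_index <- as.integer(mature_index)
  L <- mature_length(ref)
  if (any(is.na(mature_index)) || any(mature_index < 1L) ||
      any(mature_index > L)) {
    stop("mature_index out of range [1, ", L, "] for '", ref$name, "'")
  }
  L - mature_index
}
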