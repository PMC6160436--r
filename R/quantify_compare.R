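#' tRNA abundance from uniquely aligned reads
#'
#' Counts uniquely placed reads per reference and expresses each as a
#' fraction of the pool (references with zero reads are kept). Abundance
#' is best taken from demethylase-treated libraries, whose longer reads
#' make tRNA assignment specific.
#'
#' @param x A `trna_alignment`, records data.frame, or SAM path.
#' @param refset The `trna_reference_set`.
#' @return A data.frame with columns ref, unique_reads, fraction.
#' @export
trna_abundance <- function(x, refset) {
  stopifnot(inherits(refset, "trna_reference_set"))
  rec <- alignment_records(x)
  rec <- rec[rec$unique, , drop = FALSE]
  if (!nrow(rec)) stop("no uniquely aligned reads: cannot quantify")
  counts <- vapply(names(refset$references), function(nm)
    sum(rec$ref_name == nm), integer(1))
  data.frame(ref = names(counts), unique_reads = unname(counts),
             fraction = unname(counts) / sum(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Heteroplasmy fraction at a variant site
#'
#' The mutant allele fraction at a genomic variant position, computed from
#' read-throughs only: alt-base calls over (ref-base + alt-base) calls.
#' RT-stop reads carry no base call at the site and are uninformative
#' about the allele; calls that are neither allele are reported separately
#' as error mass.
#'
#' @param table A `position_table` from [build_position_table()].
#' @param ref Reference name (e.g. "MT-TK").
#' @param mature_index 1-based mature-sequence index of the variant.
#' @param ref_base,alt_base The two alleles (e.g. "A", "G" for m.8344 A>G).
#' @param min_coverage Minimum read-throughs required to report a fraction.
#' @return A list: `fraction` (NA when flagged), `n_ref`, `n_alt`,
#'   `n_other`, `flagged`.
#' @export
heteroplasmy_fraction <- function(table, ref, mature_index, ref_base,
                                  alt_base, min_coverage = 50L) {
  stopifnot(inherits(table, "position_table"))
  row <- table[table$ref == ref & table$pos == mature_index, , drop = FALSE]
  if (nrow(row) != 1L) stop("site ", ref, ":", mature_index,
                            " not present in the position table")
  count_of <- function(b) switch(b, A = row$nA, C = row$nC, G = row$nG,
                                 T = row$nT,
                                 stop("base must be one of A/C/G/T"))
  n_ref <- count_of(ref_base)
  n_alt <- count_of(alt_base)
  n_other <- row$R - n_ref - n_alt
  flagged <- row$R < min_coverage
  list(fraction = if (flagged || n_ref + n_alt == 0L) NA_real_
                  else n_alt / (n_ref + n_alt),
       n_ref = n_ref, n_alt = n_alt, n_other = n_other, flagged = flagged)
}

#' Pairwise Pearson correlation across replicate vectors
#'
#' @param tables A list (>= 2) of equal-length named numeric vectors --
#'   abundance fractions or MI values -- matched on the same items.
#' @return The pairwise Pearson r matrix; a zero-variance vector yields NA
#'   in its row/column, with a warning.
#' @export
replicate_correlation <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  lens <- vapply(tables, length, integer(1))
  if (length(unique(lens)) != 1L) stop("vectors must have equal length")
  nms <- lapply(tables, names)
  if (!is.null(nms[[1]])) {
    same <- vapply(nms, identical, logical(1), nms[[1]])
    if (!all(same)) stop("vectors must be matched on identical item names")
  }
  m <- do.call(cbind, tables)
  if (is.null(colnames(m))) colnames(m) <- paste0("rep", seq_along(tables))
  zero_var <- apply(m, 2L, sd) == 0
  if (any(zero_var)) {
    warning("zero-variance vector(s): ",
            paste(colnames(m)[zero_var], collapse = ", "),
            "; correlations reported as NA")
  }
  suppressWarnings(cor(m, method = "pearson"))
}

#' Paired t test between matched condition vectors
#'
#' Replicate-paired comparison (e.g. wild-type vs MERRF per tRNA):
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences, two-sided
#' p from the t distribution with `n - 1` df. Zero-variance differences
#' leave t undefined (reported as NA with a note). Raw p-values are the
#' primary output; no multiplicity correction is applied here.
#'
#' @param condition_a,condition_b Equal-length numeric vectors paired by
#'   replicate, `n >= 2`.
#' @return A one-row data.frame: means and SDs per condition, mean
#'   difference, t, df, p, n, note.
#' @export
paired_t_compare <- function(condition_a, condition_b) {
  n <- length(condition_a)
  if (length(condition_b) != n) stop("conditions must have equal length")
  if (n < 2L) stop("need at least 2 replicate pairs")
  d <- condition_a - condition_b
  out <- data.frame(mean_a = mean(condition_a), sd_a = sd(condition_a),
                    mean_b = mean(condition_b), sd_b = sd(condition_b),
                    mean_diff = mean(d), t = NA_real_, df = n - 1L,
                    p = NA_real_, n = n, note = "", stringsAsFactors = FALSE)
  if (sd(d) == 0) {
    out$note <- if (all(d == 0)) "no difference (zero-variance)" else
      "zero-variance differences; t undefined"
    return(out)
  }
  tt <- stats::t.test(condition_a, condition_b, paired = TRUE)
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out
}

#' Proportion of a stop product in a primer-extension assay
#'
#' Quantifies a gel-based primer-extension readout as the intensity of the
#' modification stop product over the total informative signal,
#' `a / (a + b)` -- e.g. the m1A stop at m.8348 over (m.8348 + the G stop
#' at m.8342 or m.8344).
#'
#' @param intensity_site Stop-product intensity at the modified site.
#' @param intensity_control Intensity of the downstream control stop.
#' @return The proportion in \[0, 1\].
#' @export
primer_extension_proportion <- function(intensity_site, intensity_control) {
  if (intensity_site < 0 || intensity_control < 0) {
    stop("intensities must be non-negative")
  }
  if (intensity_site + intensity_control == 0) {
    stop("both intensities are zero: proportion undefined")
  }
  intensity_site / (intensity_site + intensity_control)
}
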