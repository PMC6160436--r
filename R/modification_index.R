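#' Combine stop and mutation fractions into a Modification Index
#'
#' The Modification Index at a position is the sum of the RT-stop fraction
#' and the mutation fraction, both taken over the same denominator (reads
#' that reached the position), so the MI is bounded in \[0, 1\]. A sum
#' exceeding 1 signals inconsistent denominators and is an error, never
#' silently clipped.
#'
#' @param stop_fraction,mutation_fraction Numeric vectors in \[0, 1\] (NA
#'   allowed for uncovered positions).
#' @return `stop_fraction + mutation_fraction`.
#' @export
modification_index <- function(stop_fraction, mutation_fraction) {
  ok <- !is.na(stop_fraction) & !is.na(mutation_fraction)
  if (any(stop_fraction[ok] < 0 | stop_fraction[ok] > 1) ||
      any(mutation_fraction[ok] < 0 | mutation_fraction[ok] > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  mi <- stop_fraction + mutation_fraction
  if (any(mi[ok] > 1 + 1e-9)) {
    stop("stop + mutation fraction exceeds 1: the two fractions must ",
         "share the reached-read denominator")
  }
  mi
}

#' Build the per-position table behind a position sequencing plot
#'
#' From uniquely aligned reads, counts at every mature position `p`:
#' read-throughs `R(p)` (reads covering `p`), stops `S(p)` (reads whose
#' 5'-most covered position is `p + 1`; a stop "at p" means `p` was not
#' copied), the reached denominator `N(p) = S(p) + R(p)`, base calls over
#' read-throughs, and mutated read-throughs `X(p)`. Stop, mutation and MI
#' fractions all use `N(p)`. Positions within `lb_threshold` nt of the 3'
#' end are flagged: there, RT-stop cDNAs are too short for the library, so
#' the MI is only a lower bound of the modification fraction.
#'
#' @param x A `trna_alignment`, its `records` data.frame, or a SAM path
#'   written by [write_sam()].
#' @param refset The `trna_reference_set`.
#' @param min_coverage Positions with `N(p)` below this are flagged
#'   `coverage_ok = FALSE` and excluded from modification calls.
#' @param lb_threshold Distance to the 3' end (nt) below which stop
#'   fractions are unreliable (default 25).
#' @return A `position_table` data.frame, one row per reference position,
#'   with attributes `full_length` and `aligned_unique` (per-reference
#'   read accounting).
#' @export
build_position_table <- function(x, refset, min_coverage = 50L,
                                 lb_threshold = 25L) {
  stopifnot(inherits(refset, "trna_reference_set"))
  rec <- alignment_records(x)
  rec <- rec[rec$unique, , drop = FALSE]
  bad <- setdiff(unique(rec$ref_name), names(refset$references))
  if (length(bad)) {
    stop("alignments reference tRNAs absent from the set: ",
         paste(bad, collapse = ", "))
  }
  tabs <- lapply(names(refset$references), function(nm) {
    ref <- refset$references[[nm]]
    L <- mature_length(ref)
    r <- rec[rec$ref_name == nm, , drop = FALSE]
    S <- integer(L)
    cov <- integer(L)
    X <- integer(L)
    base_counts <- matrix(0L, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    if (nrow(r)) {
      stops <- r$start[r$start > 1L] - 1L
      S <- tabulate(stops, nbins = L)
      ds <- tabulate(r$start, nbins = L)
      de <- tabulate(r$end + 1L, nbins = L + 1L)
      cov <- cumsum(ds - de[seq_len(L)])
      mm_rows <- which(r$n_mismatch > 0L & nzchar(r$mismatches))
      if (length(mm_rows)) {
        entries <- unlist(strsplit(r$mismatches[mm_rows], ";", fixed = TRUE),
                          use.names = FALSE)
        mm_pos <- as.integer(sub(":.*$", "", entries))
        mm_alt <- sub("^.*>", "", entries)
        X <- tabulate(mm_pos, nbins = L)
        for (b in colnames(base_counts)) {
          base_counts[, b] <- tabulate(mm_pos[mm_alt == b], nbins = L)
        }
      }
    }
    ref_chars <- strsplit(ref$mature_seq, "")[[1]]
    # read-throughs carrying the reference base
    for (b in colnames(base_counts)) {
      at_b <- ref_chars == b
      base_counts[at_b, b] <- base_counts[at_b, b] +
        (cov[at_b] - X[at_b])
    }
    N <- S + cov
    stop_frac <- ifelse(N > 0L, S / N, NA_real_)
    mut_frac <- ifelse(N > 0L, X / N, NA_real_)
    conv <- rep(NA_integer_, L)
    if (length(ref$numbering_map)) {
      conv[ref$numbering_map] <- as.integer(names(ref$numbering_map))
    }
    data.frame(ref = nm, pos = seq_len(L), ref_base = ref_chars,
               conv_pos = conv, N = N, S = S, R = cov, X = X,
               nA = base_counts[, "A"], nC = base_counts[, "C"],
               nG = base_counts[, "G"], nT = base_counts[, "T"],
               stop_frac = stop_frac, mut_frac = mut_frac,
               MI = modification_index(stop_frac, mut_frac),
               dist3p = L - seq_len(L),
               lower_bound = (L - seq_len(L)) < lb_threshold,
               coverage_ok = N >= min_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  full_len <- vapply(names(refset$references), function(nm)
    sum(rec$ref_name == nm & rec$start == 1L), integer(1))
  aligned <- vapply(names(refset$references), function(nm)
    sum(rec$ref_name == nm), integer(1))
  attr(out, "full_length") <- full_len
  attr(out, "aligned_unique") <- aligned
  class(out) <- c("position_table", "data.frame")
  out
}

alignment_records <- function(x) {
  if (inherits(x, "trna_alignment")) return(x$records)
  if (is.character(x) && length(x) == 1L) return(read_sam(x)$records)
  if (is.data.frame(x)) return(x)
  stop("expected a trna_alignment, records data.frame, or SAM path")
}

#' Re-flag 3'-proximal lower-bound positions
#'
#' @param table A `position_table`.
#' @param threshold Distance to the 3' end below which the MI is only a
#'   lower bound (set 0 to clear all flags).
#' @return The table with `lower_bound` recomputed.
#' @export
flag_lower_bound <- function(table, threshold = 25L) {
  stopifnot(inherits(table, "position_table"))
  table$lower_bound <- table$dist3p < threshold
  table
}

#' Call modification signatures from matched untreated/treated tables
#'
#' Demethylase treatment erases methyl marks on the Watson-Crick face: a
#' position whose untreated MI is at least `mi_min` but collapses to at
#' most `treated_max` after treatment is called
#' `demethylase_sensitive_methyl`. Signal surviving treatment in both
#' libraries (`MI >= mi_min` in both) is `non_methyl_signal` (e.g. the
#' 2-thio wobble perturbation); everything else is `unmodified`. Calls are
#' signature classes, not chemical identities.
#'
#' @param table_untreated,table_treated `position_table`s built on the same
#'   reference set.
#' @param mi_min Minimum untreated MI to call a site (default 0.1).
#' @param treated_max Maximum treated MI compatible with full erasure
#'   (default 0.05).
#' @return A data.frame with one row per position covered adequately in
#'   both libraries: MI in each, `delta`, the `call`, and the
#'   `lower_bound` flag.
#' @export
call_modifications <- function(table_untreated, table_treated,
                               mi_min = 0.1, treated_max = 0.05) {
  stopifnot(inherits(table_untreated, "position_table"),
            inherits(table_treated, "position_table"))
  if (!identical(paste(table_untreated$ref, table_untreated$pos),
                 paste(table_treated$ref, table_treated$pos))) {
    stop("tables were not built on identical references")
  }
  ok <- table_untreated$coverage_ok & table_treated$coverage_ok &
    !is.na(table_untreated$MI) & !is.na(table_treated$MI)
  u <- table_untreated[ok, , drop = FALSE]
  t <- table_treated[ok, , drop = FALSE]
  call <- rep("unmodified", nrow(u))
  call[u$MI >= mi_min & t$MI <= treated_max] <- "demethylase_sensitive_methyl"
  call[u$MI >= mi_min & t$MI >= mi_min] <- "non_methyl_signal"
  out <- data.frame(ref = u$ref, pos = u$pos, conv_pos = u$conv_pos,
                    MI_untreated = u$MI, MI_treated = t$MI,
                    delta = u$MI - t$MI, call = call,
                    lower_bound = u$lower_bound, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate a modified fraction from a mutation-only MI
#'
#' For a site too close to the 3' end for its RT stops to survive library
#' construction, the observed MI is the mutation component alone. If a
#' context-matched site suggests the fraction of total signal contributed
#' by mutations (`mutation_share`), the modified fraction can be estimated
#' as `mutation_only_MI / mutation_share`. With the equal-contribution
#' default (0.5), a mutation-only MI of 0.24 gives 0.48; the empirical
#' share of a context-matched site (e.g. 0.074/0.16) may be supplied
#' instead.
#'
#' @param mutation_only_MI Observed mutation-only MI, in \[0, 1\].
#' @param mutation_share Fraction of total modification signal attributed
#'   to mutations, in (0, 1\].
#' @return The estimated modified fraction, capped at 1 with a warning.
#' @export
estimate_modified_fraction <- function(mutation_only_MI,
                                       mutation_share = 0.5) {
  if (any(mutation_share <= 0) || any(mutation_share > 1)) {
    stop("mutation_share must lie in (0, 1]")
  }
  if (any(mutation_only_MI < 0 | mutation_only_MI > 1)) {
    stop("mutation_only_MI must lie in [0, 1]")
  }
  est <- mutation_only_MI / mutation_share
  if (any(est > 1)) {
    warning("estimated fraction exceeds 1; capping at 1")
    est <- pmin(est, 1)
  }
  est
}
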