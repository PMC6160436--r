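#' Describe one modified site for simulation
#'
#' Ground truth for the simulator: a site is modified on a random fraction
#' `f` of molecules; on a modified template the reverse transcriptase
#' terminates with probability `s` (the read then covers positions strictly
#' 3' of the site) or reads through, misincorporating with probability `m`.
#' Demethylase-sensitive marks (m1A/m1G/m3C class) lose both signatures
#' under treatment; 2-thio-perturbed sites such as the wobble
#' taurinomethyl-2-thiouridine do not.
#'
#' @param ref_name Reference the site lives on.
#' @param mature_index 1-based mature-sequence index of the site.
#' @param f Modified fraction of molecules, in \[0, 1\].
#' @param s RT-stop probability given a modified template.
#' @param m Misincorporation probability given read-through of a modified
#'   template.
#' @param mut_base Base written on misincorporation: a fixed base or
#'   `"random"` for a uniform draw over the three non-reference bases.
#' @param demethylase_sensitive Logical; `TRUE` for methyl marks erased by
#'   demethylase treatment.
#' @return A `mod_profile` list.
#' @export
mod_profile <- function(ref_name, mature_index, f, s, m,
                        mut_base = "random", demethylase_sensitive = TRUE) {
  stopifnot(f >= 0, f <= 1, s >= 0, s <= 1, m >= 0, m <= 1)
  structure(list(ref_name = ref_name,
                 mature_index = as.integer(mature_index),
                 f = f, s = s, m = m, mut_base = mut_base,
                 demethylase_sensitive = isTRUE(demethylase_sensitive)),
            class = "mod_profile")
}

#' Describe the 3' oligo(A) tail model
#'
#' @param pool Which molecules receive tails: `"cca_absent"` (default;
#'   mirrors the observation that oligoadenylation is essentially confined
#'   to the CCA-lacking pool), `"both"`, or `"none"`.
#' @param dist `"geometric"` (lengths `rgeom` with the given mean, so length
#'   0 is possible) or `"fixed"`.
#' @param mean Mean of the geometric length distribution.
#' @param len Fixed tail length when `dist = "fixed"`.
#' @return An `oligoA_spec` list.
#' @export
oligoA_spec <- function(pool = c("cca_absent", "both", "none"),
                        dist = c("geometric", "fixed"), mean = 3, len = 0L) {
  pool <- match.arg(pool)
  dist <- match.arg(dist)
  stopifnot(mean >= 0, len >= 0)
  structure(list(pool = pool, dist = dist, mean = mean, len = as.integer(len)),
            class = "oligoA_spec")
}

#' Configure a synthetic DM-tRNA-seq library
#'
#' The generator emulates the defining features of DM-tRNA-seq read data:
#' cDNA synthesis starts at the molecule 3' terminus (all reads are
#' 3'-anchored), premature termination and misincorporation at modified
#' template positions, erasure of methyl signatures by demethylase
#' treatment, sub-stoichiometric modification, mitochondrial heteroplasmy,
#' CCA-present/absent 3' ends with optional oligo(A) tails, uniform
#' per-base sequencing error, and loss (with resampling) of cDNAs shorter
#' than the minimum insert length.
#'
#' @param refset A `trna_reference_set`.
#' @param reads_per_ref Named numeric vector: exact read counts per
#'   reference, or relative abundances when `total_reads` is given (the
#'   library is then drawn multinomially, so replicate libraries under
#'   different seeds show realistic sampling noise).
#' @param total_reads Optional total library size accompanying relative
#'   abundances in `reads_per_ref`.
#' @param profiles List of [mod_profile()] objects.
#' @param heteroplasmy Optional data.frame with columns `ref`,
#'   `mature_index`, `alt_base`, `fraction`: genomic variants applied to
#'   each molecule with the given fraction (e.g. m.8344 A>G).
#' @param cca_absent_fraction Scalar or named-per-reference fraction of
#'   molecules lacking the 3' CCA.
#' @param oligoA An [oligoA_spec()].
#' @param seq_error_rate Per-base sequencing error probability.
#' @param min_insert_len cDNAs shorter than this are lost from the library
#'   and resampled; this is what makes 3'-proximal stop fractions a lower
#'   bound.
#' @param demethylase_treated Logical; if `TRUE`, demethylase-sensitive
#'   profiles contribute neither stops nor misincorporations.
#' @param rng_seed Integer seed; fixed seed reproduces the library exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(refset, reads_per_ref, total_reads = NULL,
                       profiles = list(),
                       heteroplasmy = NULL, cca_absent_fraction = 0,
                       oligoA = oligoA_spec(), seq_error_rate = 0,
                       min_insert_len = 15L, demethylase_treated = FALSE,
                       rng_seed = 1L) {
  stopifnot(inherits(refset, "trna_reference_set"))
  if (is.null(names(reads_per_ref)) || any(!nzchar(names(reads_per_ref)))) {
    stop("reads_per_ref must be a named vector")
  }
  missing_refs <- setdiff(names(reads_per_ref), names(refset$references))
  if (length(missing_refs)) {
    stop("reads_per_ref names absent from reference set: ",
         paste(missing_refs, collapse = ", "))
  }
  for (p in profiles) {
    stopifnot(inherits(p, "mod_profile"))
    if (!p$ref_name %in% names(refset$references)) {
      stop("profile references unknown tRNA '", p$ref_name, "'")
    }
    glen <- gene_length(refset$references[[p$ref_name]])
    if (p$mature_index < 1L || p$mature_index > glen) {
      stop("profile index ", p$mature_index, " outside gene body of '",
           p$ref_name, "'")
    }
  }
  if (!is.null(heteroplasmy)) {
    need <- c("ref", "mature_index", "alt_base", "fraction")
    miss <- setdiff(need, names(heteroplasmy))
    if (length(miss)) stop("heteroplasmy missing columns: ",
                           paste(miss, collapse = ", "))
    if (any(heteroplasmy$fraction < 0 | heteroplasmy$fraction > 1)) {
      stop("heteroplasmy fractions must lie in [0, 1]")
    }
    bad <- setdiff(heteroplasmy$ref, names(refset$references))
    if (length(bad)) stop("heteroplasmy references unknown tRNA: ",
                          paste(bad, collapse = ", "))
  }
  if (any(cca_absent_fraction < 0 | cca_absent_fraction > 1)) {
    stop("cca_absent_fraction must lie in [0, 1]")
  }
  if (seq_error_rate < 0 || seq_error_rate > 1) {
    stop("seq_error_rate must lie in [0, 1]")
  }
  min_insert_len <- as.integer(min_insert_len)
  if (is.na(min_insert_len) || min_insert_len < 1L) {
    stop("min_insert_len must be >= 1")
  }
  if (!is.null(total_reads)) {
    total_reads <- as.integer(total_reads)
    if (is.na(total_reads) || total_reads < 1L) {
      stop("total_reads must be a positive integer")
    }
    if (any(reads_per_ref < 0) || sum(reads_per_ref) <= 0) {
      stop("relative abundances must be non-negative with positive sum")
    }
  }
  structure(
    list(refset = refset,
         reads_per_ref = if (is.null(total_reads)) {
           setNames(as.integer(reads_per_ref), names(reads_per_ref))
         } else {
           setNames(as.numeric(reads_per_ref), names(reads_per_ref))
         },
         total_reads = total_reads,
         profiles = profiles, heteroplasmy = heteroplasmy,
         cca_absent_fraction = cca_absent_fraction, oligoA = oligoA,
         seq_error_rate = seq_error_rate, min_insert_len = min_insert_len,
         demethylase_treated = isTRUE(demethylase_treated),
         rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

cca_fraction_for <- function(config, ref_name) {
  p <- config$cca_absent_fraction
  if (!is.null(names(p))) {
    if (ref_name %in% names(p)) unname(p[[ref_name]]) else 0
  } else {
    p
  }
}

draw_tail_lengths <- function(n, eligible, spec) {
  out <- integer(n)
  if (spec$pool == "none" || !any(eligible)) return(out)
  k <- sum(eligible)
  out[eligible] <- if (spec$dist == "geometric") {
    rgeom(k, 1 / (1 + spec$mean))
  } else {
    rep.int(spec$len, k)
  }
  out
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# One batch of n candidate molecules for a single reference; no insert-length
# filtering here. Returns sense-orientation sequences plus the truth table.
generate_batch <- function(ref, n, config) {
  glen <- gene_length(ref)
  L <- mature_length(ref)
  base_chars <- strsplit(ref$mature_seq, "")[[1]]

  cca_absent <- rbinom(n, 1L, cca_fraction_for(config, ref$name)) == 1L
  body_end <- ifelse(cca_absent, glen, L)
  eligible <- switch(config$oligoA$pool,
                     cca_absent = cca_absent,
                     both = rep(TRUE, n),
                     none = rep(FALSE, n))
  tail_len <- draw_tail_lengths(n, eligible, config$oligoA)

  het <- config$heteroplasmy
  if (!is.null(het)) het <- het[het$ref == ref$name, , drop = FALSE]
  n_het <- if (is.null(het)) 0L else nrow(het)
  het_drawn <- if (n_het) {
    vapply(seq_len(n_het),
           function(k) rbinom(n, 1L, het$fraction[k]) == 1L, logical(n))
  } else NULL
  if (n == 1L && n_het) het_drawn <- matrix(het_drawn, nrow = 1L)

  prof <- Filter(function(p) p$ref_name == ref$name, config$profiles)
  if (length(prof)) {
    prof <- prof[order(vapply(prof, `[[`, integer(1), "mature_index"),
                       decreasing = TRUE)]
  }
  stop_pos <- integer(n)             # 0 = read-through to the 5' end
  mut_flag <- matrix(FALSE, n, max(1L, length(prof)))
  # cDNA synthesis proceeds 3' -> 5': the 3'-most stop wins; positions 5'
  # of a stop are never copied ("stop at p" means p itself is not copied).
  for (j in seq_along(prof)) {
    p <- prof[[j]]
    f_eff <- if (config$demethylase_treated && p$demethylase_sensitive) 0 else p$f
    modified <- rbinom(n, 1L, f_eff) == 1L
    stopped <- modified & rbinom(n, 1L, p$s) == 1L
    hit <- stopped & stop_pos == 0L
    stop_pos[hit] <- p$mature_index
    mut_flag[, j] <- modified & !stopped & rbinom(n, 1L, p$m) == 1L
  }

  read_len <- body_end - stop_pos + tail_len
  n_err <- if (config$seq_error_rate > 0) {
    rbinom(n, read_len, config$seq_error_rate)
  } else integer(n)

  seqs <- character(n)
  mut_desc <- character(n)
  var_desc <- character(n)
  err_desc <- character(n)
  for (i in seq_len(n)) {
    off <- stop_pos[i]
    s <- if (off < body_end[i]) {
      base_chars[seq.int(off + 1L, body_end[i])]
    } else character(0)  # stop at the body 3' terminus: nothing copied
    if (n_het) {
      for (k in seq_len(n_het)) {
        v <- het$mature_index[k]
        if (het_drawn[i, k]) {
          var_desc[i] <- paste0(var_desc[i],
                                if (nzchar(var_desc[i])) ";", v, ":",
                                base_chars[v], ">", het$alt_base[k])
          if (v > off && v <= body_end[i]) s[v - off] <- het$alt_base[k]
        }
      }
    }
    muts <- character()
    for (j in seq_along(prof)) {
      if (mut_flag[i, j]) {
        p <- prof[[j]]
        idx <- p$mature_index
        if (idx > off) {
          ref_b <- base_chars[idx]
          new_b <- if (identical(p$mut_base, "random")) {
            sample(OTHER_BASES[[ref_b]], 1L)
          } else p$mut_base
          s[idx - off] <- new_b
          muts <- c(muts, paste0(idx, ":", ref_b, ">", new_b))
        }
      }
    }
    mut_desc[i] <- paste(muts, collapse = ";")
    if (tail_len[i] > 0L) s <- c(s, rep.int("A", tail_len[i]))
    if (n_err[i] > 0L) {
      pos <- sample.int(length(s), n_err[i])
      errs <- character(n_err[i])
      for (e in seq_along(pos)) {
        old <- s[pos[e]]
        s[pos[e]] <- sample(OTHER_BASES[[old]], 1L)
        body_len <- body_end[i] - off
        errs[e] <- if (pos[e] <= body_len) {
          paste0(pos[e] + off, ":", old, ">", s[pos[e]])
        } else {
          paste0("tail+", pos[e] - body_len, ":", old, ">", s[pos[e]])
        }
      }
      err_desc[i] <- paste(errs, collapse = ";")
    }
    seqs[i] <- paste(s, collapse = "")
  }

  list(seq_sense = seqs,
       truth = data.frame(
         ref = ref$name,
         stop = ifelse(stop_pos == 0L, "full", as.character(stop_pos)),
         mut_pos = mut_desc, cca = !cca_absent, tail_len = tail_len,
         variant = var_desc, seq_error = err_desc, read_len = read_len,
         stringsAsFactors = FALSE),
       read_len = read_len)
}

# Keep drawing molecules until n survive the minimum-insert filter;
# resampling keeps the library size exact while recording how many short
# cDNAs were lost (the auditable 3'-proximal lower-bound effect).
simulate_ref_reads <- function(ref, n, config, max_rounds = 60L) {
  kept_seq <- character(0)
  kept_truth <- NULL
  discarded <- 0L
  need <- n
  for (round in seq_len(max_rounds)) {
    b <- generate_batch(ref, need, config)
    ok <- b$read_len >= config$min_insert_len
    discarded <- discarded + sum(!ok)
    kept_seq <- c(kept_seq, b$seq_sense[ok])
    kept_truth <- rbind(kept_truth, b$truth[ok, , drop = FALSE])
    need <- n - length(kept_seq)
    if (need == 0L) break
  }
  if (need > 0L) {
    stop("could not draw ", n, " reads of >= ", config$min_insert_len,
         " nt for '", ref$name, "': nearly all cDNAs fall below the ",
         "minimum insert length under this configuration")
  }
  list(seq_sense = kept_seq, truth = kept_truth, discarded = discarded)
}

#' Simulate a single sequencing-ready molecule
#'
#' Draws molecules under `config` until one survives the minimum-insert
#' filter and returns it with its full truth record. Uses the current RNG
#' state (call `set.seed()` for reproducibility); [simulate_library()] seeds
#' itself from `config$rng_seed`.
#'
#' @param ref A `trna_reference` present in `config$refset`.
#' @param config A [sim_config()].
#' @return List with `seq_sense` (tRNA-sense read), `seq_read` (the stored
#'   cDNA-orientation sequence, reverse complement of sense) and `truth`
#'   (one-row data.frame).
#' @export
simulate_molecule <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!ref$name %in% names(config$refset$references)) {
    stop("reference '", ref$name, "' not in the configured reference set")
  }
  out <- simulate_ref_reads(ref, 1L, config)
  list(seq_sense = out$seq_sense,
       seq_read = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(out$seq_sense))),
       truth = out$truth)
}

#' Simulate a DM-tRNA-seq library
#'
#' Generates all configured reads, writes them as a 4-line FASTQ (constant
#' quality "I"; the pipeline is quality-agnostic) in cDNA orientation --
#' the reverse complement of tRNA sense, as a TGIRT cDNA library is
#' sequenced -- plus a per-read ground-truth TSV. Byte-identical output
#' under a fixed `rng_seed`.
#'
#' @param config A [sim_config()].
#' @param fastq Optional output FASTQ path.
#' @param truth_tsv Optional output truth TSV path.
#' @return Invisibly, a list with `reads` (named character vector, cDNA
#'   orientation), `truth` (data.frame, one row per read) and `discarded`
#'   (named count of short cDNAs lost and resampled per reference).
#' @export
simulate_library <- function(config, fastq = NULL, truth_tsv = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  refs <- config$refset$references
  counts <- config$reads_per_ref
  if (!is.null(config$total_reads)) {
    counts <- setNames(as.integer(stats::rmultinom(
      1L, config$total_reads, counts / sum(counts))[, 1L]), names(counts))
  }
  all_seq <- character(0)
  all_truth <- NULL
  discarded <- setNames(integer(length(counts)), names(counts))
  for (nm in names(counts)) {
    n <- counts[[nm]]
    if (n == 0L) next
    out <- simulate_ref_reads(refs[[nm]], n, config)
    ids <- sprintf("%s|r%06d", nm, seq_len(n))
    names(out$seq_sense) <- ids
    out$truth <- cbind(read_id = ids, out$truth, stringsAsFactors = FALSE)
    all_seq <- c(all_seq, out$seq_sense)
    all_truth <- rbind(all_truth, out$truth)
    discarded[[nm]] <- out$discarded
  }
  if (!length(all_seq)) stop("configuration yields zero reads")
  reads <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_seq)))
  names(reads) <- names(all_seq)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth_tsv)) {
    write.table(all_truth, truth_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(reads = reads, truth = all_truth, discarded = discarded))
}

write_fastq <- function(reads, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  rec <- paste0("@", names(reads), "\n", reads, "\n+\n",
                strrep("I", nchar(reads)))
  writeLines(rec, con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
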