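# Flat "key = value" run-configuration files; '#' starts a comment.
parse_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("unparseable config line ", which(bad)[1], ": '", lines[bad][1], "'")
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}

run_config_defaults <- function() {
  list(seed = 1L, min_len = 15L, max_mismatch = 3L, max_hits = 10L,
       polyA_n = 30L, min_coverage = 50L, lb_threshold = 25L,
       mi_min = 0.1, treated_max = 0.05, simulate = FALSE,
       reads_per_sample = 2000L, seq_error_rate = 0.001,
       cca_absent_fraction = 0.05, oligoA_mean = 3, min_insert_len = 15L)
}

#' Validate a pipeline run configuration
#'
#' Parses a flat key = value configuration file, applies defaults, checks
#' every referenced path and every numeric bound, and validates the sample
#' sheet (columns sample_id, condition, replicate, treated, fastq; fastq
#' may be "-" when `simulate = true`). All problems are collected and
#' returned together, never first-failure.
#'
#' @param path Path to the configuration file.
#' @return A list with `ok` (logical), `errors` (character vector) and,
#'   when valid, `config` (a `run_config` object).
#' @export
validate_config <- function(path) {
  raw <- parse_run_config(path)
  cfg <- run_config_defaults()
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  base_dir <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    if (is.null(p) || !nzchar(p)) return(p)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  num_keys <- c("seed", "min_len", "max_mismatch", "max_hits", "polyA_n",
                "min_coverage", "lb_threshold", "mi_min", "treated_max",
                "reads_per_sample", "seq_error_rate", "cca_absent_fraction",
                "oligoA_mean", "min_insert_len")
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k %in% num_keys) {
      nv <- suppressWarnings(as.numeric(v))
      if (is.na(nv)) note(paste0("key '", k, "': not a number ('", v, "')"))
      else cfg[[k]] <- nv
    } else if (k == "simulate") {
      cfg$simulate <- tolower(v) %in% c("true", "yes", "1")
    } else {
      cfg[[k]] <- v
    }
  }
  for (k in c("refs_fasta", "samplesheet")) {
    if (is.null(cfg[[k]])) note(paste0("required key '", k, "' missing"))
  }
  for (k in c("refs_fasta", "refs_meta", "samplesheet", "profiles",
              "heteroplasmy")) {
    if (!is.null(cfg[[k]])) {
      cfg[[k]] <- resolve(cfg[[k]])
      if (!file.exists(cfg[[k]])) {
        note(paste0("key '", k, "': file not found (", cfg[[k]], ")"))
      }
    }
  }
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate > 1) {
    note("seq_error_rate must lie in [0, 1]")
  }
  if (cfg$cca_absent_fraction < 0 || cfg$cca_absent_fraction > 1) {
    note("cca_absent_fraction must lie in [0, 1]")
  }
  for (k in c("min_len", "max_mismatch", "max_hits", "polyA_n",
              "min_coverage", "lb_threshold", "reads_per_sample",
              "min_insert_len")) {
    if (cfg[[k]] < 0) note(paste0(k, " must be non-negative"))
  }
  sheet <- NULL
  if (!is.null(cfg$samplesheet) && file.exists(cfg$samplesheet)) {
    sheet <- read.delim(cfg$samplesheet, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "replicate", "treated", "fastq")
    miss <- setdiff(need, names(sheet))
    if (length(miss)) {
      note(paste0("sample sheet missing columns: ",
                  paste(miss, collapse = ", ")))
    } else {
      if (anyDuplicated(sheet$sample_id)) {
        note(paste0("duplicate sample ids: ",
                    paste(unique(sheet$sample_id[
                      duplicated(sheet$sample_id)]), collapse = ", ")))
      }
      if (!all(tolower(sheet$treated) %in% c("yes", "no"))) {
        note("sample sheet 'treated' must be yes/no")
      }
      real <- sheet$fastq != "-"
      if (any(real)) {
        paths <- vapply(sheet$fastq[real], resolve, character(1))
        gone <- !file.exists(paths)
        if (any(gone)) note(paste0("fastq not found: ",
                                   paste(paths[gone], collapse = ", ")))
        sheet$fastq[real] <- paths
      }
      if (any(!real) && !cfg$simulate) {
        note("sample sheet uses '-' fastq entries but simulate is not true")
      }
    }
  }
  cfg$sheet <- sheet
  if (length(errors)) return(list(ok = FALSE, errors = errors))
  class(cfg) <- "run_config"
  list(ok = TRUE, errors = character(0), config = cfg)
}

read_profile_table <- function(path, refset) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref", "mature_index", "f", "s", "m", "demethylase_sensitive")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("profiles table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"condition" %in% names(tab)) tab$condition <- "all"
  if (!"mut_base" %in% names(tab)) tab$mut_base <- "random"
  tab
}

profiles_for_condition <- function(tab, condition) {
  if (is.null(tab)) return(list())
  keep <- tab$condition == condition | tab$condition == "all"
  lapply(which(keep), function(i)
    mod_profile(tab$ref[i], tab$mature_index[i], tab$f[i], tab$s[i],
                tab$m[i], mut_base = tab$mut_base[i],
                demethylase_sensitive = isTRUE(as.logical(
                  tab$demethylase_sensitive[i]))))
}

het_for_condition <- function(tab, condition) {
  if (is.null(tab)) return(NULL)
  keep <- tab$condition == condition | tab$condition == "all"
  out <- tab[keep, c("ref", "mature_index", "alt_base", "fraction")]
  if (!nrow(out)) NULL else out
}

# Sum count columns across replicate tables and recompute the fractions.
aggregate_position_tables <- function(tables) {
  out <- tables[[1]]
  cnt <- c("N", "S", "R", "X", "nA", "nC", "nG", "nT")
  for (t in tables[-1]) {
    stopifnot(identical(paste(t$ref, t$pos), paste(out$ref, out$pos)))
    out[cnt] <- out[cnt] + t[cnt]
  }
  out$stop_frac <- ifelse(out$N > 0, out$S / out$N, NA_real_)
  out$mut_frac <- ifelse(out$N > 0, out$X / out$N, NA_real_)
  out$MI <- modification_index(out$stop_frac, out$mut_frac)
  mc <- attr(tables[[1]], "min_coverage")
  out$coverage_ok <- out$N >= if (is.null(mc)) 50L else mc
  class(out) <- c("position_table", "data.frame")
  out
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full DM-tRNA-seq analysis pipeline
#'
#' Orchestrates, per sample: read input (or simulate it when the sample
#' sheet says so), length filtering, best-stratum alignment with poly-A
#' remapping, SAM + alignment-summary output, position table, tail
#' classification and adenylation table, and abundance. Then, per
#' condition: replicate-aggregated treated/untreated modification calls;
#' across conditions: per-tRNA abundance paired t tests and replicate
#' correlations. Writes a parameter manifest (with input checksums) and a
#' plain-text report. All artifacts are TSV/SAM/FASTQ, so every stage is
#' independently inspectable. A fixed seed makes the run byte-reproducible.
#'
#' @param config A validated `run_config` (from [validate_config()]) or a
#'   path to a configuration file.
#' @param out_dir Output directory (created; defaults to the config's
#'   `out_dir` or a "results" sibling of the config file).
#' @return The output directory, invisibly. On stage failure the run
#'   aborts naming the stage and sample, leaving partial outputs and a
#'   FAILED marker.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    v <- validate_config(config)
    if (!v$ok) stop("invalid configuration:\n  - ",
                    paste(v$errors, collapse = "\n  - "))
    config <- v$config
  }
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) {
    out_dir <- if (!is.null(config$out_dir)) config$out_dir else "results"
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, sample, e) {
    writeLines(paste0("FAILED at stage '", stage, "' sample '", sample,
                      "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed for sample '", sample,
         "': ", conditionMessage(e))
  }
  logf <- file.path(out_dir, "run.log")
  say <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  }
  unlink(logf)

  refset <- tryCatch(
    load_references(config$refs_fasta, config$refs_meta,
                    polyA_n = config$polyA_n),
    error = function(e) fail("references", "-", e))
  say("references", sprintf("%d references loaded",
                            length(refset$references)))
  prof_tab <- if (!is.null(config$profiles)) {
    read_profile_table(config$profiles, refset)
  }
  het_tab <- if (!is.null(config$heteroplasmy)) {
    read.delim(config$heteroplasmy, stringsAsFactors = FALSE)
  }
  if (!is.null(het_tab) && !"condition" %in% names(het_tab)) {
    het_tab$condition <- "all"
  }
  sheet <- config$sheet

  tables <- list(); abund <- list(); sam_paths <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    treated <- tolower(sheet$treated[i]) == "yes"
    reads <- tryCatch({
      if (sheet$fastq[i] == "-") {
        sc <- sim_config(
          refset, default_abundance_weights(refset),
          total_reads = config$reads_per_sample,
          profiles = profiles_for_condition(prof_tab, sheet$condition[i]),
          heteroplasmy = het_for_condition(het_tab, sheet$condition[i]),
          cca_absent_fraction = config$cca_absent_fraction,
          oligoA = oligoA_spec(mean = config$oligoA_mean),
          seq_error_rate = config$seq_error_rate,
          min_insert_len = config$min_insert_len,
          demethylase_treated = treated,
          rng_seed = (config$seed * 1000L + i) %% .Machine$integer.max)
        fq <- file.path(out_dir, paste0(sid, ".fastq"))
        sim <- simulate_library(sc, fastq = fq,
                                truth_tsv = file.path(
                                  out_dir, paste0(sid, ".truth.tsv")))
        sim$reads
      } else {
        read_fastq(sheet$fastq[i])
      }
    }, error = function(e) fail("reads", sid, e))
    say("reads", sprintf("%s: %d reads", sid, length(reads)))

    aln <- tryCatch({
      kept <- length_filter(reads, config$min_len)
      say("length_filter", sprintf("%s: removed %d short reads", sid,
                                   attr(kept, "n_removed")))
      align_reads(kept, refset, max_mismatch = config$max_mismatch,
                  max_hits = config$max_hits)
    }, error = function(e) fail("align", sid, e))
    sam <- file.path(out_dir, paste0(sid, ".sam"))
    write_sam(aln, refset, sam, reads = reads)
    write_tsv(aln$summary, file.path(out_dir, paste0(sid, ".alnsummary.tsv")))
    sam_paths[[sid]] <- sam
    say("align", sprintf("%s: %d unique / %d aligned / %d suppressed / %d unaligned",
                         sid, aln$summary$unique, aln$summary$aligned,
                         aln$summary$suppressed, aln$summary$unaligned))

    tab <- tryCatch(
      build_position_table(aln, refset, min_coverage = config$min_coverage,
                           lb_threshold = config$lb_threshold),
      error = function(e) fail("position_table", sid, e))
    attr(tab, "min_coverage") <- config$min_coverage
    write_tsv(tab, file.path(out_dir, paste0(sid, ".positions.tsv")))
    tables[[sid]] <- tab

    tails <- tryCatch(classify_tails(aln, refset),
                      error = function(e) fail("tails", sid, e))
    write_tsv(tails, file.path(out_dir, paste0(sid, ".tails.tsv")))
    write_tsv(adenylation_frequency(tails),
              file.path(out_dir, paste0(sid, ".adenylation.tsv")))
    abund[[sid]] <- trna_abundance(aln, refset)
    write_tsv(abund[[sid]], file.path(out_dir, paste0(sid, ".abundance.tsv")))
  }

  # per-condition modification calls from replicate-aggregated tables
  conditions <- unique(sheet$condition)
  calls <- list()
  for (cond in conditions) {
    u_ids <- sheet$sample_id[sheet$condition == cond &
                               tolower(sheet$treated) == "no"]
    t_ids <- sheet$sample_id[sheet$condition == cond &
                               tolower(sheet$treated) == "yes"]
    if (length(u_ids) && length(t_ids)) {
      calls[[cond]] <- call_modifications(
        aggregate_position_tables(tables[u_ids]),
        aggregate_position_tables(tables[t_ids]),
        mi_min = config$mi_min, treated_max = config$treated_max)
      write_tsv(calls[[cond]],
                file.path(out_dir, paste0("calls.", cond, ".tsv")))
    }
  }

  # abundance comparison between the first two conditions, paired by replicate
  comparison <- NULL
  if (length(conditions) >= 2L) {
    quant_for <- function(cond) {
      ids <- sheet$sample_id[sheet$condition == cond &
                               tolower(sheet$treated) == "yes"]
      if (!length(ids)) {
        warning("no demethylase-treated libraries for condition '", cond,
                "'; quantifying from untreated")
        ids <- sheet$sample_id[sheet$condition == cond]
      }
      reps <- sheet$replicate[match(ids, sheet$sample_id)]
      ids[order(reps)]
    }
    a_ids <- quant_for(conditions[1])
    b_ids <- quant_for(conditions[2])
    np <- min(length(a_ids), length(b_ids))
    if (np >= 2L) {
      refs <- abund[[a_ids[1]]]$ref
      rows <- lapply(refs, function(rf) {
        av <- vapply(a_ids[seq_len(np)], function(s)
          abund[[s]]$fraction[abund[[s]]$ref == rf], numeric(1))
        bv <- vapply(b_ids[seq_len(np)], function(s)
          abund[[s]]$fraction[abund[[s]]$ref == rf], numeric(1))
        cbind(data.frame(ref = rf, stringsAsFactors = FALSE),
              paired_t_compare(av, bv))
      })
      comparison <- do.call(rbind, rows)
      comparison$p_BH <- stats::p.adjust(comparison$p, method = "BH")
      write_tsv(comparison, file.path(out_dir, "abundance.comparison.tsv"))
    }
    for (cond in conditions[1:2]) {
      ids <- quant_for(cond)
      if (length(ids) >= 2L) {
        vecs <- lapply(ids, function(s)
          setNames(abund[[s]]$fraction, abund[[s]]$ref))
        names(vecs) <- ids
        write_tsv(as.data.frame(replicate_correlation(vecs)),
                  file.path(out_dir,
                            paste0("correlation.", cond, ".tsv")))
      }
    }
  }

  manifest <- c(
    sprintf("dmtrnaseq %s", as.character(packageVersion("dmtrnaseq"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "parameters:",
    vapply(setdiff(names(unclass(config)), "sheet"), function(k)
      sprintf("  %s = %s", k, paste(format(config[[k]]), collapse = " ")),
      character(1)),
    "input checksums:",
    vapply(Filter(function(p) is.character(p) && length(p) == 1 &&
                    file.exists(p),
                  unclass(config)[c("refs_fasta", "refs_meta", "samplesheet",
                                    "profiles", "heteroplasmy")]),
           function(p) sprintf("  %s  %s", tools::md5sum(p), p),
           character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  write_report(out_dir, sheet, abund, calls, comparison)
  invisible(out_dir)
}

write_report <- function(out_dir, sheet, abund, calls, comparison) {
  rep <- c("dmtrnaseq run report", strrep("=", 60), "")
  rep <- c(rep, "Samples:", vapply(seq_len(nrow(sheet)), function(i)
    sprintf("  %s  condition=%s rep=%s treated=%s", sheet$sample_id[i],
            sheet$condition[i], sheet$replicate[i], sheet$treated[i]),
    character(1)), "")
  for (cond in names(calls)) {
    cc <- calls[[cond]]
    hits <- cc[cc$call != "unmodified", , drop = FALSE]
    hits <- hits[order(-hits$MI_untreated), , drop = FALSE]
    rep <- c(rep, sprintf("Modification calls, condition %s:", cond))
    if (!nrow(hits)) {
      rep <- c(rep, "  (none above threshold)")
    } else {
      rep <- c(rep, vapply(seq_len(min(nrow(hits), 15L)), function(i)
        sprintf("  %s pos %d%s  MI %.3f -> %.3f  %s%s", hits$ref[i],
                hits$pos[i],
                if (!is.na(hits$conv_pos[i]))
                  sprintf(" (conv %d)", hits$conv_pos[i]) else "",
                hits$MI_untreated[i], hits$MI_treated[i], hits$call[i],
                if (hits$lower_bound[i]) " [3'-proximal lower bound]" else ""),
        character(1)))
    }
    rep <- c(rep, "")
  }
  if (!is.null(comparison)) {
    sig <- comparison[!is.na(comparison$p) & comparison$p < 0.05, ,
                      drop = FALSE]
    rep <- c(rep, "Abundance comparison (condition 1 vs 2, paired t):",
             if (nrow(sig)) vapply(seq_len(nrow(sig)), function(i)
               sprintf("  %s  mean %.4f vs %.4f  t=%.2f p=%.3g", sig$ref[i],
                       sig$mean_a[i], sig$mean_b[i], sig$t[i], sig$p[i]),
               character(1))
             else "  (no tRNA at p < 0.05)", "")
  }
  writeLines(rep, file.path(out_dir, "report.txt"))
}
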