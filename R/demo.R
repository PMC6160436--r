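# Fixed log-spread relative abundances (~15-fold range) used when the
# pipeline simulates libraries: realistic inter-tRNA spread, deterministic
# across runs so replicate variation comes only from multinomial sampling.
default_abundance_weights <- function(refset) {
  n <- length(refset$references)
  setNames(exp(seq(log(0.2), log(3), length.out = n)),
           names(refset$references))
}

#' Write a ready-to-run demo configuration
#'
#' Materialises a complete simulated study into `dir`: the packaged
#' synthetic mitochondrial tRNA references, a modification-profile table
#' planting an m1A58-like demethylase-sensitive site on MT-TK in the "WT"
#' condition only (absent in "MERRF"), shared m1A9- and m1A16-like sites,
#' a wobble 2-thio-like demethylase-insensitive signal reduced in MERRF,
#' the m.8344 A>G heteroplasmy in MERRF, a sample sheet (two conditions x
#' `n_replicates` x treated/untreated, all simulated), and the flat
#' key = value run configuration consumed by [run_pipeline()].
#'
#' @param dir Directory to write into (created).
#' @param reads_per_sample Reads simulated per library.
#' @param n_replicates Replicates per condition.
#' @param seed Base seed for the run.
#' @return The configuration file path.
#' @export
demo_run_config <- function(dir, reads_per_sample = 3300L,
                            n_replicates = 3L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- system.file("extdata", "mt_trna_synthetic.fa", package = "dmtrnaseq")
  meta <- system.file("extdata", "mt_trna_synthetic_meta.tsv",
                      package = "dmtrnaseq")
  profiles <- data.frame(
    ref = c("MT-TK", "MT-TK", "MT-TK", "MT-TK", "MT-TR"),
    mature_index = c(54L, 9L, 34L, 34L, 16L),
    f = c(0.5, 0.9, 0.9, 0.35, 0.18),
    s = c(0.45, 0.45, 0, 0, 0.45),
    m = c(0.45, 0.45, 0.25, 0.25, 0.45),
    mut_base = "random",
    demethylase_sensitive = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    condition = c("WT", "all", "WT", "MERRF", "all"),
    stringsAsFactors = FALSE)
  write_tsv(profiles, file.path(dir, "profiles.tsv"))
  het <- data.frame(ref = "MT-TK", mature_index = 50L, alt_base = "G",
                    fraction = 0.8, condition = "MERRF",
                    stringsAsFactors = FALSE)
  write_tsv(het, file.path(dir, "heteroplasmy.tsv"))
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      treated = c("no", "yes"),
                      condition = c("WT", "MERRF"),
                      stringsAsFactors = FALSE)
  sheet <- data.frame(
    sample_id = sprintf("%s_rep%d_%s", rows$condition, rows$replicate,
                        ifelse(rows$treated == "yes", "dem", "untr")),
    condition = rows$condition, replicate = rows$replicate,
    treated = rows$treated, fastq = "-", stringsAsFactors = FALSE)
  write_tsv(sheet, file.path(dir, "samplesheet.tsv"))
  cfg <- file.path(dir, "run_config.txt")
  writeLines(c(
    "# dmtrnaseq demo run: simulated WT vs MERRF, treated/untreated",
    paste0("refs_fasta = ", fa),
    paste0("refs_meta = ", meta),
    "samplesheet = samplesheet.tsv",
    "profiles = profiles.tsv",
    "heteroplasmy = heteroplasmy.tsv",
    "simulate = true",
    paste0("reads_per_sample = ", reads_per_sample),
    paste0("seed = ", seed),
    "seq_error_rate = 0.001",
    "cca_absent_fraction = 0.05",
    "oligoA_mean = 3",
    paste0("out_dir = ", file.path(dir, "results"))), cfg)
  cfg
}
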