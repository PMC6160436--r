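# One-off generator for the synthetic mitochondrial tRNA reference fixture.
set.seed(42)
names22 <- c("MT-TA","MT-TC","MT-TD","MT-TE","MT-TF","MT-TG","MT-TH",
             "MT-TI","MT-TK","MT-TL1","MT-TL2","MT-TM","MT-TN","MT-TP",
             "MT-TQ","MT-TR","MT-TS1","MT-TS2","MT-TT","MT-TV","MT-TW",
             "MT-TY")
l_strand <- c("MT-TA","MT-TC","MT-TE","MT-TN","MT-TP","MT-TQ","MT-TS2",
              "MT-TY")
# rough genomic 5' coordinates for labeling only
starts <- c(5587,5761,7518,14674,577,9991,12138,4263,8295,3230,12266,
            4402,5657,15956,4329,10405,7446,12207,15888,1602,5512,5826)
lens <- sample(63:72, 22, replace = TRUE)
lens[names22 == "MT-TK"] <- 70L
lens[names22 == "MT-TR"] <- 65L

rand_gene <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
seqs <- vapply(lens, rand_gene, character(1))

put <- function(s, i, b) { substr(s, i, i) <- b; s }
k <- which(names22 == "MT-TK")
seqs[k] <- put(seqs[k], 9, "A")    # m1A9 site
seqs[k] <- put(seqs[k], 34, "T")   # U34 wobble
seqs[k] <- put(seqs[k], 50, "A")   # m.8344 (genome_start 8295 + 49)
seqs[k] <- put(seqs[k], 54, "A")   # m1A58 site (m.8348), context ACA
seqs[k] <- put(seqs[k], 55, "C")
seqs[k] <- put(seqs[k], 56, "A")
r <- which(names22 == "MT-TR")
seqs[r] <- put(seqs[r], 16, "A")   # m1A16 site, context ACA
seqs[r] <- put(seqs[r], 17, "C")
seqs[r] <- put(seqs[r], 18, "A")
seqs[r] <- put(seqs[r], 9, "A")

numbering <- rep("9:9;34:34", 22)
numbering[k] <- "9:9;34:34;58:54"
numbering[r] <- "9:9;16:16;34:34"

fa <- file("inst/extdata/mt_trna_synthetic.fa", "wb")
writeLines(paste0(">", names22, "\n", seqs), fa); close(fa)
meta <- data.frame(name = names22,
                   strand = ifelse(names22 %in% l_strand, "L", "H"),
                   genome_start = starts, numbering = numbering)
write.table(meta, "inst/extdata/mt_trna_synthetic_meta.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("gene lengths:", paste(lens, collapse = ","), "\n")
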