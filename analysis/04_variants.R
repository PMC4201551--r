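#!/usr/bin/env Rscript
# Variant census: align each mapping-consensus to the reference, extract
# and classify variants, annotate homopolymer context, and summarize the
# platform indel bias.
source(file.path("analysis", "00_config.R"))

ref <- read_fasta(file.path(DATA_DIR, "reference.fasta"), as = "plastome")

for (nm in c("illumina", "iontorrent")) {
  cons <- read_fasta(file.path(OUT_DIR, paste0(nm, "_consensus.fasta")),
                     as = "plastome")
  v <- extract_variants(align_consensus(cons$sequence, ref))
  v <- annotate_homopolymer(v, ref)
  snp <- sum(v$type == "SNP")
  cat(sprintf("%s: %d variants vs reference (%d SNP: %d ts / %d tv; %d MNV; %d ins; %d del)\n",
              nm, nrow(v), snp,
              sum(v$substitution_class == "transition", na.rm = TRUE),
              sum(v$substitution_class == "transversion", na.rm = TRUE),
              sum(v$type == "MNV"), sum(v$type == "ins"),
              sum(v$type == "del")))
  b <- summarize_bias(v)
  cat(sprintf("%s: %d indels in homopolymer context (GC %d / AT %d)\n",
              nm, b$n, b$totals["GC"], b$totals["AT"]))
  write_variant_table(v, file.path(OUT_DIR, paste0(nm, "_variants.tsv")))
  write.table(b$by, file.path(OUT_DIR, paste0(nm, "_indel_bias.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cen <- homopolymer_census(ref$sequence, base_filter = "GC", min_length = 7)
cat("reference GC homopolymer census (>= 7 bp): ",
    paste(names(cen), cen, sep = "bp x", collapse = ", "), "\n")
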