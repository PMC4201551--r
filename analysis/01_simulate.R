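#!/usr/bin/env Rscript
# Build the synthetic two-platform study set: a reference plastome, a
# "wild" genotype carrying an implanted truth variant set, and shotgun
# reads from both platform presets.
source(file.path("analysis", "00_config.R"))

ref <- reference_genome()
cat(sprintf("reference plastome: %d bp, GC %.1f%%, IR %d bp x2\n",
            nchar(ref$sequence), 100 * gc_content(ref$sequence), IR_LENGTH))

iv <- implant_variants(ref, variant_load(GENOME_LENGTH))
cat(sprintf("wild genotype: %d truth variants (%s)\n", nrow(iv$truth),
            paste(names(table(iv$truth$type)), table(iv$truth$type),
                  sep = "=", collapse = ", ")))

illumina <- simulate_reads(iv$sequence, illumina_error_model(), COVERAGE,
                           seed = GLOBAL_SEED + 11L)
iontorrent <- simulate_reads(iv$sequence, iontorrent_error_model(), COVERAGE,
                             seed = GLOBAL_SEED + 12L)
for (nm in c("illumina", "iontorrent")) {
  rs <- get(nm)
  el <- attr(rs, "error_log")
  cat(sprintf("%s: %d reads, %.2f%% simulated per-base error (%d sub / %d del / %d ins)\n",
              nm, length(rs), 100 * nrow(el) / sum(nchar(rs$bases)),
              sum(el$kind == "sub"), sum(el$kind == "del"),
              sum(el$kind == "ins")))
}

write_fasta(ref, file.path(DATA_DIR, "reference.fasta"))
write_fasta(setNames(iv$sequence, "wild_truth"),
            file.path(DATA_DIR, "wild_truth.fasta"))
write_variant_table(iv$truth, file.path(DATA_DIR, "truth_variants.tsv"))
write_fastq(illumina, file.path(DATA_DIR, "illumina.fastq"))
write_fastq(iontorrent, file.path(DATA_DIR, "iontorrent.fastq"))
cat("wrote reference, truth and FASTQ files under", DATA_DIR, "\n")
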