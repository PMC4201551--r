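#!/usr/bin/env Rscript
# Per-platform de novo assembly, contig polishing, scaffolding against the
# reference (allowing non-unique IR matches), and joining.
source(file.path("analysis", "00_config.R"))

ref <- read_fasta(file.path(DATA_DIR, "reference.fasta"), as = "plastome")
limits <- c(illumina = 0.01, iontorrent = 0.05)

for (nm in names(limits)) {
  rs <- read_fastq(file.path(DATA_DIR, paste0(nm, ".fastq")), platform = nm)
  tr <- trim_set(rs, trim_params(limit = limits[[nm]]))$reads
  ctg <- assemble(tr, assembly_params(k = 21))
  pol <- polish_contigs(ctg, tr, mapping_params(), seed = GLOBAL_SEED + 31L)
  sal <- align_contigs(pol, ref)
  jj <- join_contigs(sal, pol, ref)
  cat(sprintf("%s: %d contigs (longest %d bp), %d placements, join -> %s\n",
              nm, nrow(pol), if (nrow(pol)) max(nchar(pol$seq)) else 0,
              nrow(sal), jj$type))
  if (nrow(pol))
    write_fasta(pol, file.path(OUT_DIR, paste0(nm, "_contigs.fasta")))
  write.table(sal[, setdiff(names(sal), "oriented")],
              file.path(OUT_DIR, paste0(nm, "_scaffolds.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (jj$type == "consensus") {
    write_fasta(setNames(jj$sequence, paste0(nm, "_denovo_consensus")),
                file.path(OUT_DIR, paste0(nm, "_denovo.fasta")))
  } else {
    write.table(jj$gaps, file.path(OUT_DIR, paste0(nm, "_gaps.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%s: %d gap(s) prevented joining\n", nm, nrow(jj$gaps)))
  }
}
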