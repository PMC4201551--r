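# Shared settings for the analysis scripts. The study is run on a synthetic
# plastome so that every stage has a known truth; sizes are scaled to a
# laptop-friendly 30 kb genome at 50x per platform (the pipeline itself
# handles full 130 kb plastomes the same way).

library(cpbarcode)

GLOBAL_SEED <- 20260923L
GENOME_LENGTH <- 30000L
IR_LENGTH <- 4000L
COVERAGE <- 50

DATA_DIR <- file.path("results", "data")
OUT_DIR <- file.path("results")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# wild-genotype truth: a study-scale variant load, scaled to genome size
variant_load <- function(L) {
  f <- L / 130000
  variant_spec(n_snp = max(1, round(92 * f)), n_mnv = max(1, round(5 * f)),
               n_ins = max(1, round(13 * f)), n_del = max(1, round(18 * f)),
               seed = GLOBAL_SEED + 2L)
}

reference_genome <- function() {
  generate_plastome(genome_spec(length = GENOME_LENGTH, ir_length = IR_LENGTH,
                                seed = GLOBAL_SEED))
}
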