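test_that("plastome generation is deterministic and honors its spec", {
  a <- generate_plastome(genome_spec(length = 10000, ir_length = 0, seed = 1))
  b <- generate_plastome(genome_spec(length = 10000, ir_length = 0, seed = 1))
  expect_identical(a$sequence, b$sequence)
  expect_equal(nchar(a$sequence), 10000)

  g <- generate_plastome(genome_spec(length = 12000, ir_length = 2000, seed = 3))
  ir1 <- substr(g$sequence, g$ir_regions[[1]][1], g$ir_regions[[1]][2])
  ir2 <- substr(g$sequence, g$ir_regions[[2]][1], g$ir_regions[[2]][2])
  expect_identical(ir2, revcomp(ir1))

  big <- generate_plastome(genome_spec(length = 100000, ir_length = 0, seed = 5))
  expect_gt(gc_content(big$sequence), 0.37)
  expect_lt(gc_content(big$sequence), 0.41)

  # homopolymer spectrum admits long runs
  census <- homopolymer_census(big$sequence, min_length = 10)
  expect_gt(sum(census), 0)
  expect_s3_class(tryCatch(genome_spec(length = 10000, ir_length = 6000),
                           error = identity), "cpb_parameter_error")
})

test_that("variant implantation realizes counts exactly and reconstructs", {
  g <- generate_plastome(genome_spec(length = 60000, ir_length = 8000, seed = 2))
  iv <- implant_variants(g, variant_spec(seed = 7))   # study-scale defaults
  expect_equal(nrow(iv$truth), 128)
  expect_equal(sum(iv$truth$type == "SNP"), 92)
  expect_equal(sum(iv$truth$type == "MNV"), 5)
  expect_equal(sum(iv$truth$type == "ins"), 13)
  expect_equal(sum(iv$truth$type == "del"), 18)
  expect_false(is.unsorted(iv$truth$position))
  # truth applied to the original reconstructs the mutated sequence
  expect_identical(apply_variants(g$sequence, iv$truth), iv$sequence)
  # empty spec is the identity
  iv0 <- implant_variants(g, variant_spec(n_snp = 0, n_mnv = 0, n_ins = 0,
                                          n_del = 0, seed = 1))
  expect_identical(iv0$sequence, g$sequence)
  expect_equal(nrow(iv0$truth), 0)
})

test_that("error-free simulation yields exact genome substrings", {
  g <- generate_plastome(genome_spec(length = 5000, ir_length = 0, seed = 4))
  rs <- simulate_reads(g, illumina_error_model(substitution_rate = 0),
                       coverage = 5, seed = 9)
  expect_gt(length(rs), 0)
  fwd <- rs$bases
  hit <- vapply(seq_along(fwd), function(i)
    grepl(fwd[i], g$sequence, fixed = TRUE) ||
      grepl(revcomp(fwd[i]), g$sequence, fixed = TRUE), logical(1))
  expect_true(all(hit))
  # determinism and coverage accounting
  rs2 <- simulate_reads(g, illumina_error_model(substitution_rate = 0),
                        coverage = 5, seed = 9)
  expect_identical(rs$bases, rs2$bases)
  expect_lt(abs(sum(nchar(rs$bases)) - 5 * 5000) / (5 * 5000), 0.05)
})

test_that("substitution errors match the binomial model", {
  g <- generate_plastome(genome_spec(length = 10000, ir_length = 0, seed = 6))
  rs <- simulate_reads(g, illumina_error_model(), coverage = 50, seed = 10)
  el <- attr(rs, "error_log")
  n_bases <- sum(nchar(rs$bases))
  n_sub <- sum(el$kind == "sub")
  ci <- qbinom(c(0.005, 0.995), n_bases, 0.001)
  expect_gte(n_sub, ci[1])
  expect_lte(n_sub, ci[2])
  expect_equal(sum(el$kind %in% c("del", "ins")), 0)
})

test_that("the semiconductor preset is indel-dominated with the right bias", {
  g <- generate_plastome(genome_spec(length = 30000, ir_length = 0, seed = 8))
  rs <- simulate_reads(g, iontorrent_error_model(), coverage = 10, seed = 11)
  expect_gt(sum(nchar(rs$bases)), 1e5)
  el <- attr(rs, "error_log")
  n_indel <- sum(el$kind %in% c("del", "ins"))
  expect_gt(n_indel, sum(el$kind == "sub"))
  dl <- el[el$kind == "del", ]
  ins <- el[el$kind == "ins", ]
  # deletions enriched in short GC runs, insertions in long AT runs
  expect_gt(mean(dl$class == "GC" & dl$run_length <= 5), 0.5)
  expect_gt(mean(ins$class == "AT" & ins$run_length >= 5), 0.5)
  # claimed qualities match the platform preset
  expect_gt(mean(unlist(rs$quals)), 24)
  expect_lt(mean(unlist(rs$quals)), 27)
})

test_that("paired simulation emits proper mates with sampled inserts", {
  g <- generate_plastome(genome_spec(length = 20000, ir_length = 0, seed = 12))
  rs <- simulate_reads(g, illumina_error_model(substitution_rate = 0),
                       coverage = 8, seed = 13)
  expect_true(all(!is.na(rs$mate)))
  expect_setequal(unique(rs$mate), c(1L, 2L))
  m1 <- which(rs$mate == 1L)
  m2 <- which(rs$mate == 2L)[match(rs$pair_id[m1], rs$pair_id[rs$mate == 2L])]
  # mate 1 forward, mate 2 reverse-complemented: both locate on the genome
  s1 <- vapply(m1[1:20], function(i)
    as.integer(regexpr(rs$bases[i], g$sequence, fixed = TRUE)), integer(1))
  s2 <- vapply(m2[1:20], function(i)
    as.integer(regexpr(revcomp(rs$bases[i]), g$sequence, fixed = TRUE)),
    integer(1))
  expect_true(all(s1 > 0) && all(s2 > 0))
  inserts <- s2 + 100 - s1
  expect_gt(mean(inserts), 450)
  expect_lt(mean(inserts), 650)
  # mean claimed PHRED within the short-read preset band
  expect_gt(mean(unlist(rs$quals)), 29)
  expect_lt(mean(unlist(rs$quals)), 32)
})
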