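test_that("error-free coverage assembles a repeat-free genome into one contig", {
  set.seed(51)
  src <- random_seq(5000)
  starts <- sample(1:(5000 - 99), 2500, replace = TRUE)
  bases <- substring(src, starts, starts + 99)
  flip <- sample(length(bases), 1250)
  bases[flip] <- revcomp(bases[flip])
  rs <- read_set(sprintf("a%04d", seq_along(bases)), bases,
                 lapply(bases, function(b) rep(35L, 100)))
  ctg <- assemble(rs, assembly_params(k = 21))
  expect_equal(nrow(ctg), 1)
  expect_gte(nchar(ctg$seq[1]), 5000 - 20)        # up to k-1 terminal bases
  expect_true(grepl(ctg$seq[1], src, fixed = TRUE) ||
                grepl(ctg$seq[1], revcomp(src), fixed = TRUE))
  expect_gt(ctg$mean_depth[1], 30)
})

test_that("identical long repeats break the assembly graph", {
  set.seed(52)
  rep2k <- random_seq(2000)
  src <- paste0(random_seq(2000), rep2k, random_seq(2000), rep2k,
                random_seq(2000))
  starts <- sample(1:(nchar(src) - 99), 5000, replace = TRUE)
  bases <- substring(src, starts, starts + 99)
  rs <- read_set(sprintf("b%04d", seq_along(bases)), bases,
                 lapply(bases, function(b) rep(35L, 100)))
  ctg <- assemble(rs, assembly_params(k = 21))
  expect_gt(nrow(ctg), 1)
})

test_that("contigs below the minimum length are discarded", {
  set.seed(53)
  src <- random_seq(150)
  bases <- substring(src, seq(1, 101, by = 2), seq(50, 150, by = 2))
  rs <- read_set(sprintf("c%03d", seq_along(bases)), bases,
                 lapply(bases, function(b) rep(35L, nchar(b))))
  ctg <- assemble(rs, assembly_params(k = 15, min_contig_length = 200))
  expect_equal(nrow(ctg), 0)
  ctg2 <- assemble(rs, assembly_params(k = 15, min_contig_length = 100))
  expect_gt(nrow(ctg2), 0)
})

test_that("the auto word size rule clips into [15, 31] and stays odd", {
  expect_true(cpbarcode:::auto_k(1e4) >= 15)
  expect_true(cpbarcode:::auto_k(1e12) %% 2 == 1)
  expect_lte(cpbarcode:::auto_k(1e30), 31)
  expect_s3_class(tryCatch(assembly_params(k = 16), error = identity),
                  "cpb_parameter_error")
})

test_that("polishing corrects an introduced error and flags orphan contigs", {
  set.seed(54)
  src <- random_seq(3000)
  starts <- sample(1:(3000 - 99), 1500, replace = TRUE)
  bases <- substring(src, starts, starts + 99)
  rs <- read_set(sprintf("p%04d", seq_along(bases)), bases,
                 lapply(bases, function(b) rep(35L, 100)))
  broken <- mutate_bases(src, 1500)
  ctg <- data.frame(id = c("good", "orphan"),
                    seq = c(broken, random_seq(400)),
                    mean_depth = c(50, 0), stringsAsFactors = FALSE)
  pol <- polish_contigs(ctg, rs, mapping_params(), seed = 55)
  expect_identical(pol$seq[1], src)
  expect_identical(pol$seq[2], ctg$seq[2])
  expect_true(pol$unpolished[2])
  # a correct contig is a fixed point
  again <- polish_contigs(pol[1, 1:3], rs, mapping_params(), seed = 56)
  expect_identical(again$seq[1], src)
})

test_that("contig placement finds exact intervals and IR copies", {
  g <- generate_plastome(genome_spec(length = 20000, ir_length = 3000, seed = 57))
  ctg <- data.frame(id = "c1", seq = substr(g$sequence, 2001, 6000),
                    stringsAsFactors = FALSE)
  al <- align_contigs(ctg, g)
  expect_equal(nrow(al), 1)
  expect_equal(al$ref_start, 2001)
  expect_equal(al$ref_end, 6000)
  expect_equal(al$percent_identity, 1)
  expect_equal(al$query_coverage, 1)
  expect_true(al$unique)

  ir <- g$ir_regions[[1]]
  ctg_ir <- data.frame(id = "ir", seq = substr(g$sequence, ir[1] + 100, ir[1] + 1600),
                       stringsAsFactors = FALSE)
  al_ir <- align_contigs(ctg_ir, g, allow_nonunique = TRUE)
  expect_equal(nrow(al_ir), 2)
  expect_false(any(al_ir$unique))
  al_one <- align_contigs(ctg_ir, g, allow_nonunique = FALSE)
  expect_equal(nrow(al_one), 1)

  set.seed(58)
  junk <- data.frame(id = "junk", seq = random_seq(800), stringsAsFactors = FALSE)
  expect_equal(nrow(align_contigs(junk, g)), 0)
})

test_that("joining merges overlapping tiles and reports gaps otherwise", {
  set.seed(59)
  ref <- random_seq(10000)
  ctg <- data.frame(id = c("left", "right"),
                    seq = c(substr(ref, 1, 6000), substr(ref, 5951, 10000)),
                    stringsAsFactors = FALSE)
  al <- align_contigs(ctg, ref)
  jj <- join_contigs(al, ctg, ref)
  expect_identical(jj$type, "consensus")
  expect_identical(jj$sequence, ref)

  gap <- data.frame(id = c("left", "right"),
                    seq = c(substr(ref, 1, 6000), substr(ref, 6101, 10000)),
                    stringsAsFactors = FALSE)
  alg <- align_contigs(gap, ref)
  jg <- join_contigs(alg, gap, ref)
  expect_identical(jg$type, "gaps")
  expect_equal(jg$gaps$start, 6001)
  expect_equal(jg$gaps$end, 6100)

  # conflicting overlap raises a named error (disagreements are internal
  # to the overlap so they survive end clipping)
  bad_right <- paste0(mutate_bases(substr(ref, 5961, 6000), c(25, 30, 35)),
                      substr(ref, 6001, 10000))
  conf <- data.frame(id = c("left", "right"),
                     seq = c(substr(ref, 1, 6000), bad_right),
                     stringsAsFactors = FALSE)
  alc <- align_contigs(conf, ref)
  err <- tryCatch(join_contigs(alc, conf, ref), error = identity)
  expect_s3_class(err, "cpb_conflict_error")
})

test_that("short low-depth reads leave gaps that prevent joining", {
  g <- generate_plastome(genome_spec(length = 15000, ir_length = 2500, seed = 60))
  rs <- simulate_reads(g, illumina_error_model(read_length = 36,
                                               insert_size = c(180, 20)),
                       coverage = 7, seed = 61)
  tr <- trim_set(rs, trim_params(limit = 0.01))
  ctg <- assemble(tr$reads, assembly_params(k = 21))
  jj <- join_contigs(align_contigs(ctg, g), ctg, g)
  expect_identical(jj$type, "gaps")
  expect_gt(nrow(jj$gaps), 0)
})
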