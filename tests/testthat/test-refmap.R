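test_that("exact reads map at cost zero to their source interval", {
  set.seed(21)
  ref <- random_seq(5000)
  m <- map_read(substr(ref, 1001, 1100), ref)
  expect_identical(m$status, "mapped")
  expect_equal(m$placements$start, 1001)
  expect_equal(m$placements$end, 1100)
  expect_equal(m$placements$cost, 0)
  expect_equal(m$placements$identity, 1)
  # reverse-complement maps at the same site on the minus strand
  mrc <- map_read(revcomp(substr(ref, 1001, 1100)), ref)
  expect_equal(mrc$placements$start, 1001)
  expect_equal(mrc$placements$strand, -1)
  # too-short read
  expect_identical(map_read("ACGTACGTAC", ref)$status, "too_short")
})

test_that("acceptance thresholds separate 2 from 4 substitutions in 30 bp", {
  set.seed(22)
  ref <- random_seq(2000)
  rd <- substr(ref, 501, 530)
  rd2 <- mutate_bases(rd, c(5, 20))
  m2 <- map_read(rd2, ref)
  expect_identical(m2$status, "mapped")       # identity 28/30 >= 0.9
  expect_equal(m2$placements$cost, 4)
  expect_equal(m2$placements$cost, map_cost_oracle(rd2, substr(ref, 301, 730)))
  rd4 <- mutate_bases(rd, c(3, 11, 19, 27))
  expect_identical(map_read(rd4, ref)$status, "unmapped")  # 26/30 < 0.9
})

test_that("mapping cost equals the full-DP oracle on random cases", {
  set.seed(23)
  ref <- random_seq(300)
  checked <- 0
  for (t in 1:80) {
    st <- sample(1:240, 1)
    len <- sample(30:60, 1)
    rd <- substr(ref, st, min(st + len - 1, 300))
    nmut <- sample(0:3, 1)
    if (nmut) rd <- mutate_bases(rd, sample(nchar(rd), nmut))
    m <- map_read(rd, ref)
    if (m$status %in% c("mapped", "multimapped")) {
      expect_equal(m$placements$cost[1], map_cost_oracle(rd, ref))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("reads from an inverted repeat split evenly under random policy", {
  g <- generate_plastome(genome_spec(length = 12000, ir_length = 2500, seed = 24))
  ir1 <- g$ir_regions[[1]]
  set.seed(25)
  starts <- sample(ir1[1]:(ir1[2] - 99), 400, replace = TRUE)
  rs <- read_set(sprintf("ir%03d", 1:400),
                 substring(g$sequence, starts, starts + 99),
                 lapply(1:400, function(i) rep(35L, 100)))
  mp <- map_reads(rs, g, mapping_params(), seed = 26)
  expect_equal(mp$report$multimapped, 400)
  in_ir1 <- mean(mp$alignments$start >= ir1[1] - 100 &
                   mp$alignments$end <= ir1[2] + 100)
  expect_gt(in_ir1, 0.4)
  expect_lt(in_ir1, 0.6)
  # deterministic under the seed
  mp2 <- map_reads(rs, g, mapping_params(), seed = 26)
  expect_identical(mp$alignments$start, mp2$alignments$start)
  # discard policy drops them
  mpd <- map_reads(rs, g, mapping_params(multimap_policy = "discard"))
  expect_equal(nrow(mpd$alignments), 0)
})

test_that("pileups tally every aligned base and deletion exactly once", {
  al <- data.frame(read = 1:3, ref = 1L, start = c(1L, 1L, 1L),
                   end = c(10L, 10L, 10L), strand = 1L,
                   cigar = c("10=", "10=", "4=1X5="),
                   oriented = c("AAAAAAAAAA", "AAAAAAAAAA", "AAAACAAAAA"),
                   stringsAsFactors = FALSE)
  pp <- build_pileup(al, strrep("A", 20))
  expect_equal(unname(pp$counts["A", 5]), 2)
  expect_equal(unname(pp$counts["C", 5]), 1)
  expect_equal(unname(pp$depth[5]), 3)
  expect_equal(pp$width, 0.5)

  del <- data.frame(read = 1L, ref = 1L, start = 1L, end = 10L, strand = 1L,
                    cigar = "4=1D5=", oriented = "AAAAAAAAA",
                    stringsAsFactors = FALSE)
  pd <- build_pileup(del, strrep("A", 10))
  expect_equal(unname(pd$counts["-", 5]), 1)

  bad <- data.frame(read = 1L, ref = 1L, start = 95L, end = 104L, strand = 1L,
                    cigar = "10=", oriented = strrep("A", 10),
                    stringsAsFactors = FALSE)
  expect_s3_class(tryCatch(build_pileup(bad, strrep("A", 100)),
                           error = identity), "cpb_integrity_error")
})

test_that("pileup tallies equal a brute-force recount on a mapped fixture", {
  set.seed(27)
  g <- generate_plastome(genome_spec(length = 1000, ir_length = 0, seed = 28))
  rs <- simulate_reads(g, iontorrent_error_model(read_length = c(80, 5)),
                       coverage = 15, seed = 29)
  mp <- map_reads(rs, g, mapping_params(), seed = 30)
  pp <- build_pileup(mp$alignments, g)
  # recount from alignment ops independently
  recount <- matrix(0L, 5, 1000, dimnames = list(c("A", "C", "G", "T", "-")))
  for (i in seq_len(nrow(mp$alignments))) {
    a <- mp$alignments[i, ]
    ops <- regmatches(a$cigar, gregexpr("[0-9]+[=XID]", a$cigar))[[1]]
    r <- a$start; q <- 1L
    sq <- strsplit(a$oriented, "")[[1]]
    for (o in ops) {
      l <- as.integer(sub("[=XID]", "", o)); op <- sub("^[0-9]+", "", o)
      if (op %in% c("=", "X")) {
        for (t in seq_len(l)) {
          recount[sq[q], r] <- recount[sq[q], r] + 1L
          q <- q + 1L; r <- r + 1L
        }
      } else if (op == "D") {
        for (t in seq_len(l)) { recount["-", r] <- recount["-", r] + 1L; r <- r + 1L }
      } else q <- q + l
    }
  }
  expect_equal(unname(pp$counts), unname(recount))
})

test_that("majority voting recovers the truth and handles deletions/ties", {
  # zero-error round trip at >= 20x
  g <- generate_plastome(genome_spec(length = 8000, ir_length = 1500, seed = 31))
  rs <- simulate_reads(g, illumina_error_model(substitution_rate = 0),
                       coverage = 22, seed = 32)
  mp <- map_reads(rs, g, mapping_params(), seed = 33)
  cons <- call_consensus(build_pileup(mp$alignments, g))
  expect_identical(cons$sequence, g$sequence)

  # a majority deletion removes the position
  ref <- strrep("ACGT", 5)
  al <- data.frame(read = 1:6, ref = 1L, start = 1L, end = 20L, strand = 1L,
                   cigar = c(rep("9=1D10=", 5), "20="),
                   oriented = c(rep(paste0(substr(ref, 1, 9), substr(ref, 11, 20)), 5), ref),
                   stringsAsFactors = FALSE)
  cc <- call_consensus(build_pileup(al, ref))
  expect_equal(nchar(cc$sequence), 19)
  expect_identical(cc$sequence, paste0(substr(ref, 1, 9), substr(ref, 11, 20)))

  # voting ties go to the reference allele
  alt <- paste0("T", substr(ref, 2, 20))
  tie <- data.frame(read = 1:2, ref = 1L, start = 1L, end = 20L, strand = 1L,
                    cigar = c("20=", "1X19="), oriented = c(ref, alt),
                    stringsAsFactors = FALSE)
  ct <- call_consensus(build_pileup(tie, ref))
  expect_identical(ct$sequence, ref)

  # zero-coverage positions emit the reference base and are flagged
  part <- data.frame(read = 1L, ref = 1L, start = 1L, end = 10L, strand = 1L,
                     cigar = "10=", oriented = substr(ref, 1, 10),
                     stringsAsFactors = FALSE)
  cp <- call_consensus(build_pileup(part, ref))
  expect_identical(cp$sequence, ref)
  expect_equal(cp$zero_coverage, 11:20)
})

test_that("consensus length follows the deletion/insertion arithmetic", {
  # 28 single-base deletions plus two 2-base deletions and one insertion,
  # each supported by >= 80% of reads, shorten a reference by 31 - 1 bases
  set.seed(34)
  ref <- random_seq(4000)
  del1 <- seq(101, by = 120, length.out = 28)       # single-base deletions
  del2 <- c(3601, 3801)                             # two 2-base deletions
  ins1 <- 3901                                      # one single-base insertion
  reads <- list()
  n_affected <- 8; n_clean <- 2
  mk_del_read <- function(p, l) {
    s <- p - 40
    paste0(substr(ref, s, p - 1), substr(ref, p + l, p + 59))
  }
  mk_ref_read <- function(p) substr(ref, p - 40, p + 59)
  rows <- list()
  for (p in del1) {
    for (i in 1:n_affected) rows[[length(rows) + 1]] <- c(mk_del_read(p, 1), p)
    for (i in 1:n_clean) rows[[length(rows) + 1]] <- c(mk_ref_read(p), p)
  }
  for (p in del2) {
    for (i in 1:n_affected) rows[[length(rows) + 1]] <- c(mk_del_read(p, 2), p)
    for (i in 1:n_clean) rows[[length(rows) + 1]] <- c(mk_ref_read(p), p)
  }
  ins_read <- paste0(substr(ref, ins1 - 40, ins1), "A", substr(ref, ins1 + 1, ins1 + 59))
  for (i in 1:n_affected) rows[[length(rows) + 1]] <- c(ins_read, ins1)
  for (i in 1:n_clean) rows[[length(rows) + 1]] <- c(mk_ref_read(ins1), ins1)
  bases <- vapply(rows, `[`, character(1), 1)
  rs <- read_set(sprintf("d%04d", seq_along(bases)), bases,
                 lapply(bases, function(b) rep(35L, nchar(b))))
  mp <- map_reads(rs, ref, mapping_params(), seed = 35)
  cons <- call_consensus(build_pileup(mp$alignments, ref))
  expect_equal(cons$n_deletions, 32)       # 28 + 2*2 majority-deleted positions
  expect_equal(cons$ins_bases, 1)
  expect_equal(nchar(cons$sequence), 4000 - 32 + 1)
  # the general conservation identity
  expect_equal(nchar(cons$sequence),
               nchar(ref) - cons$n_deletions + cons$ins_bases)
})

test_that("empty read sets map to empty alignments with zero width", {
  mp <- map_reads(read_set(character(0), character(0), list()),
                  random_seq(500), mapping_params())
  expect_equal(nrow(mp$alignments), 0)
  expect_equal(mp$report$total, 0)
  pp <- build_pileup(mp$alignments, random_seq(500))
  expect_equal(pp$width, 0)
})
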