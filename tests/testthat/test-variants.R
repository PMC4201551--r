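test_that("consensus alignment is exact on identical and near inputs", {
  set.seed(71)
  ref <- random_seq(5000)
  al <- align_consensus(ref, ref)
  expect_equal(al$cost, 0)
  expect_equal(nrow(extract_variants(al)), 0)

  one_del <- paste0(substr(ref, 1, 2000), substr(ref, 2002, 5000))
  ald <- align_consensus(one_del, ref)
  expect_equal(ald$cost, 3)                     # open 2 + extend 1
  v <- extract_variants(ald)
  expect_equal(nrow(v), 1)
  expect_identical(v$type, "del")

  expect_s3_class(tryCatch(align_consensus(random_seq(100), random_seq(200)),
                           error = identity), "cpb_parameter_error")
})

test_that("anchored alignment cost equals full affine DP on edited pairs", {
  set.seed(72)
  for (t in 1:12) {
    a <- random_seq(2000)
    b <- a
    for (e in seq_len(sample(1:10, 1))) {
      p <- sample(100:1900, 1)
      kind <- sample(c("sub", "del", "ins"), 1)
      if (kind == "sub") b <- mutate_bases(b, p)
      else if (kind == "del") b <- paste0(substr(b, 1, p - 1),
                                          substr(b, p + 1, nchar(b)))
      else b <- paste0(substr(b, 1, p), sample(c("A", "C", "G", "T"), 1),
                       substr(b, p + 1, nchar(b)))
    }
    al <- align_consensus(b, a)
    expect_equal(al$cost, global_affine_cost_oracle(b, a))
  }
})

test_that("adjacent substitutions merge into MNVs, gaps into indels", {
  set.seed(73)
  ref <- random_seq(300)
  # two adjacent substituted columns -> one MNV (like a TT -> AA event)
  q <- ref
  alt1 <- chartr("ACGT", "TGCA", substr(ref, 100, 101))
  substr(q, 100, 101) <- alt1
  v <- extract_variants(align_consensus(q, ref))
  expect_equal(nrow(v), 1)
  expect_identical(v$type, "MNV")
  expect_identical(v$ref_allele, substr(ref, 100, 101))
  expect_identical(v$alt_allele, alt1)

  # SNPs separated by one matching base stay separate
  q2 <- mutate_bases(ref, c(150, 152))
  v2 <- extract_variants(align_consensus(q2, ref))
  expect_equal(sum(v2$type == "SNP"), 2)

  # a deleted base reports the first deleted reference position
  q3 <- paste0(substr(ref, 1, 199), substr(ref, 201, 300))
  v3 <- extract_variants(align_consensus(q3, ref))
  expect_identical(v3$type, "del")
  expect_identical(v3$alt_allele, "-")
})

test_that("substitution classification is exact over all 12 ordered pairs", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("A", "C"), "transversion")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_error(classify_substitution("A", "A"))
})

test_that("indel left-normalization shifts to the leftmost equivalent site", {
  ref <- "ACCCCGT"
  v <- data.frame(position = 4L, type = "del", ref_allele = "C",
                  alt_allele = "-", stringsAsFactors = FALSE)
  nv <- normalize_variants(v, ref)
  expect_equal(nv$position, 2L)
  vi <- data.frame(position = 5L, type = "ins", ref_allele = "-",
                   alt_allele = "C", stringsAsFactors = FALSE)
  ni <- normalize_variants(vi, ref)
  expect_equal(ni$position, 1L)
  expect_identical(ni$alt_allele, "C")
  # applying the normalized and original forms gives the same sequence
  expect_identical(apply_variants(ref, v), apply_variants(ref, nv))
  expect_identical(apply_variants(ref, vi), apply_variants(ref, ni))
})

test_that("homopolymer context finds the maximal touching run", {
  ref <- "AACCCGT"
  v <- data.frame(position = 4L, type = "del", ref_allele = "C",
                  alt_allele = "-", stringsAsFactors = FALSE)
  a <- annotate_homopolymer(v, ref)
  expect_identical(a$hp_base, "C")
  expect_equal(a$hp_run_length, 3L)
  expect_identical(a$hp_class, "GC")

  # insertion inside a 10-A run
  ref10 <- paste0("GC", strrep("A", 10), "GC")
  vi <- data.frame(position = 5L, type = "ins", ref_allele = "-",
                   alt_allele = "A", stringsAsFactors = FALSE)
  ai <- annotate_homopolymer(vi, ref10)
  expect_equal(ai$hp_run_length, 10L)
  expect_identical(ai$hp_base, "A")

  # deletion flanked by different bases has run length 1
  vd <- data.frame(position = 6L, type = "del", ref_allele = "G",
                   alt_allele = "-", stringsAsFactors = FALSE)
  ad <- annotate_homopolymer(vd, "AACCCGT")
  expect_equal(ad$hp_run_length, 1L)

  # mixed multi-base deletion is flagged
  vm <- data.frame(position = 3L, type = "del", ref_allele = "CG",
                   alt_allele = "-", stringsAsFactors = FALSE)
  am <- annotate_homopolymer(vm, "AACGAA")
  expect_true(am$hp_mixed)
})

test_that("the homopolymer census counts maximal runs only", {
  expect_identical(homopolymer_census("AAAA"), c(`4` = 1L))
  cen <- homopolymer_census("AACCCGGGGT", base_filter = "GC", min_length = 2)
  expect_identical(cen, c(`3` = 1L, `4` = 1L))
  set.seed(74)
  s <- random_seq(1000)
  cen_all <- homopolymer_census(s)
  # brute-force scanner oracle
  v <- strsplit(s, "")[[1]]
  lens <- integer(0); cur <- 1L
  for (i in 2:length(v)) {
    if (v[i] == v[i - 1]) cur <- cur + 1L
    else { lens <- c(lens, cur); cur <- 1L }
  }
  lens <- c(lens, cur)
  expect_identical(cen_all, setNames(as.integer(table(lens)),
                                     names(table(lens))))
  # total length identity
  expect_equal(sum(as.integer(names(cen_all)) * cen_all), 1000)
})

test_that("gc_content is the GC fraction and rejects empty input", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_error(gc_content(""))
})

test_that("bias summaries deduplicate and total by base class", {
  z <- summarize_bias(empty <- data.frame(position = integer(0),
                                          type = character(0),
                                          ref_allele = character(0),
                                          alt_allele = character(0)))
  expect_equal(z$n, 0)

  # a fixture of 97 indels with 53 GC-context and 44 AT-context sites
  set.seed(75)
  n_gc <- 53; n_at <- 44
  pos <- seq(10, by = 10, length.out = n_gc + n_at)
  v <- data.frame(position = pos,
                  type = rep(c("del", "ins"), length.out = n_gc + n_at),
                  ref_allele = "C", alt_allele = "-",
                  hp_base = c(rep("C", n_gc), rep("A", n_at)),
                  hp_class = c(rep("GC", n_gc), rep("AT", n_at)),
                  hp_run_length = sample(2:9, n_gc + n_at, TRUE),
                  stringsAsFactors = FALSE)
  v$ref_allele[v$type == "ins"] <- "-"
  v$alt_allele[v$type == "ins"] <- v$hp_base[v$type == "ins"]
  dup <- rbind(v, v[1:5, ])                       # duplicates are removed
  b <- summarize_bias(dup)
  expect_equal(b$n, 97)
  expect_equal(unname(b$totals["GC"]), 53)
  expect_equal(unname(b$totals["AT"]), 44)
  expect_equal(sum(b$by$n), b$n)
  expect_error(summarize_bias(v[, 1:4]), "annotate")
})

test_that("variant extraction round-trips implanted truth sets", {
  for (seed in c(81, 82, 83)) {
    g <- generate_plastome(genome_spec(length = 15000, ir_length = 2000,
                                       seed = seed))
    iv <- implant_variants(g, variant_spec(n_snp = 12, n_mnv = 2, n_ins = 3,
                                           n_del = 4, seed = seed + 100))
    got <- extract_variants(align_consensus(iv$sequence, g))
    core <- c("position", "type", "ref_allele", "alt_allele")
    expect_identical(got[, core], iv$truth[, core])
  }
})
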