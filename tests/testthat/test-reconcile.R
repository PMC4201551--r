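test_that("variant-set diffs partition into one-sided and conflicting", {
  a <- data.frame(position = 10L, type = "SNP", ref_allele = "A",
                  alt_allele = "G", stringsAsFactors = FALSE)
  b <- rbind(a, data.frame(position = 20L, type = "del", ref_allele = "C",
                           alt_allele = "-", stringsAsFactors = FALSE))
  rec <- diff_variant_sets(a, b)
  expect_equal(nrow(rec), 1)
  expect_identical(rec$category, "b_only")
  expect_equal(rec$position, 20)
  expect_identical(rec$allele_a, "C")          # platform without the variant
  expect_equal(nrow(attr(rec, "shared")), 1)

  expect_equal(nrow(diff_variant_sets(a, a)), 0)

  # same position, different type (SNP vs deletion) is one conflicting record
  sa <- data.frame(position = 30L, type = "SNP", ref_allele = "C",
                   alt_allele = "A", stringsAsFactors = FALSE)
  sb <- data.frame(position = 30L, type = "del", ref_allele = "C",
                   alt_allele = "-", stringsAsFactors = FALSE)
  rc <- diff_variant_sets(sa, sb)
  expect_identical(rc$category, "conflicting")

  # completeness: categories account for every record
  expect_equal(nrow(rec), sum(table(rec$category)))
})

test_that("the bundled case study replays its printed resolution column", {
  cs <- load_case_study()
  expect_equal(nrow(cs$table), 20)
  rec <- diff_variant_sets(cs$set_a, cs$set_b)
  expect_equal(nrow(rec), 20)
  expect_equal(unname(table(rec$category)["b_only"]), 15)
  expect_equal(unname(table(rec$category)["a_only"]), 3)
  expect_equal(unname(table(rec$category)["conflicting"]), 2)

  ev <- cs$evidence[match(rec$position, cs$evidence$position), ]
  res <- resolve_discrepancies(rec, ev)
  expect_true(all(nzchar(res$resolution)))
  expected <- cs$expected[match(rec$position, cs$table$position)]
  expect_identical(res$resolved_allele, expected)

  # the narrative rules fire as described
  expect_identical(res$rule[res$position == 57036], "R1")   # mapping artifact
  expect_identical(res$resolution[res$position == 65465], "adopt_contig")
  expect_identical(res$rule[res$position == 21808], "R3")   # homopolymer read error
  r7 <- res[res$position == 3545, ]
  expect_identical(r7$rule, "R4")                            # 10-A run, contigs disagree
  expect_identical(r7$resolution, "unresolved")
  expect_true(r7$uncertain)
})

test_that("resolution requires contig evidence and falls through in order", {
  rec <- data.frame(position = 100L, site = "point", category = "b_only",
                    type_a = NA_character_, type_b = "del",
                    ref_allele = "C", allele_a = "C", allele_b = "-",
                    stringsAsFactors = FALSE)
  ev_absent <- data.frame(mapping_ambiguity = FALSE, hp_base = "C",
                          hp_class = "GC", hp_run_length = 3L,
                          stringsAsFactors = FALSE)
  ev_absent$contig_alleles <- list(c(s1 = NA_character_, s2 = NA_character_))
  r <- resolve_discrepancies(rec, ev_absent)
  expect_identical(r$resolution, "unresolved")   # no covering contig source
  expect_identical(r$resolved_allele, "C")
  expect_true(r$uncertain)

  # contigs agreeing with exactly one platform adopt that platform (R5)
  ev_a <- ev_absent
  ev_a$contig_alleles <- list(c(s1 = "C", s2 = NA_character_))
  r5 <- resolve_discrepancies(rec, ev_a)
  expect_identical(r5$resolution, "reference")   # R3: indel in run, contigs = ref
  rec_snp <- rec
  rec_snp$type_b <- "SNP"; rec_snp$allele_b <- "T"
  r5b <- resolve_discrepancies(rec_snp, ev_a)
  expect_identical(r5b$resolution, "adopt_a")
  expect_identical(r5b$rule, "R5")
})

test_that("amending applies shared plus resolved edits with coordinates intact", {
  set.seed(91)
  ref <- random_seq(1000)
  rec <- data.frame(position = c(200L, 600L), site = c("anchor", "point"),
                    category = c("b_only", "b_only"),
                    type_a = NA_character_, type_b = c("ins", "del"),
                    ref_allele = c("-", substr(ref, 600, 600)),
                    allele_a = c("-", substr(ref, 600, 600)),
                    allele_b = c("TTTTTTTTTTTTT", "-"),
                    resolution = c("adopt_b", "adopt_b"),
                    rule = "R5",
                    resolved_allele = c("TTTTTTTTTTTTT", "-"),
                    uncertain = FALSE, stringsAsFactors = FALSE)
  am <- amend_consensus(ref, rec)
  expect_equal(nchar(am$sequence), 1000 + 13 - 1)
  expect_equal(am$length_change, 12)

  # no variants: amended equals the reference
  none <- amend_consensus(ref, rec[0, ])
  expect_identical(none$sequence, ref)

  # re-extracting variants recovers exactly the applied edits
  got <- extract_variants(align_consensus(am$sequence, ref))
  expect_equal(nrow(got), 2)
  expect_identical(sort(got$type), c("del", "ins"))

  # overlapping edits collide
  bad <- rec
  bad$position <- c(600L, 600L)
  bad$site <- c("point", "point")
  bad$ref_allele <- substr(ref, 600, 600)
  expect_s3_class(tryCatch(amend_consensus(ref, bad), error = identity),
                  "cpb_conflict_error")
})

test_that("remap validation is empty for a faithful amended sequence", {
  g <- generate_plastome(genome_spec(length = 8000, ir_length = 1200, seed = 92))
  iv <- implant_variants(g, variant_spec(n_snp = 6, n_mnv = 1, n_ins = 1,
                                         n_del = 2, seed = 93))
  rs <- simulate_reads(iv$sequence, illumina_error_model(), 25, seed = 94)
  res <- validate_by_remap(iv$sequence, rs, mapping_params(), seed = 95)
  expect_equal(nrow(res), 0)
  expect_warning(
    empty <- validate_by_remap(iv$sequence,
                               read_set(character(0), character(0), list())),
    "no reads")
  expect_equal(nrow(empty), 0)
})

test_that("contig evidence reads alleles out of scaffolded contigs", {
  g <- generate_plastome(genome_spec(length = 9000, ir_length = 0, seed = 96))
  iv <- implant_variants(g, variant_spec(n_snp = 4, n_mnv = 0, n_ins = 1,
                                         n_del = 1, seed = 97))
  ctg <- data.frame(id = "c1", seq = iv$sequence, stringsAsFactors = FALSE)
  ce <- contig_evidence(ctg, g)
  expect_true(all(ce$covered[100:8900]))
  core <- c("position", "type", "ref_allele", "alt_allele")
  expect_identical(strip_rows(ce$variants[, core]), strip_rows(iv$truth[, core]))
})
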