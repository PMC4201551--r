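# Cross-platform reconciliation: detect discrepancies between two
# platforms' variant sets, resolve each with contig and mapping evidence,
# emit the amended consensus barcode, and validate it by remapping.

site_key <- function(variants) {
  paste0(ifelse(variants$type == "ins", "i", "p"), variants$position)
}

#' Diff two variant sets into discrepancy records
#'
#' Variants are matched by left-normalized site: a point site (SNP, MNV or
#' deletion position) or an insertion anchor. Sites with an identical
#' variant in both sets are "shared" (returned as an attribute); a variant
#' in one set only is `a_only`/`b_only`; different variants at the same
#' site are `conflicting`. Matching is by site rather than by (site, type)
#' so that e.g. a SNP in one platform and a deletion in the other at the
#' same position form one conflicting record.
#'
#' @param set_a,set_b Variant data.frames (left-normalized against the same
#'   reference; see [normalize_variants()]).
#' @return A data.frame of discrepancy records: `position`, `site`,
#'   `category`, `type_a`, `type_b`, `ref_allele`, `allele_a`, `allele_b`,
#'   with shared variants in `attr(, "shared")`.
#' @export
diff_variant_sets <- function(set_a, set_b) {
  ka <- site_key(set_a)
  kb <- site_key(set_b)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    cpb_error("variant sets must have one variant per site", "cpb_parameter_error")
  all_keys <- union(ka, kb)
  rows <- list()
  shared_idx <- integer(0)
  for (key in all_keys) {
    ia <- match(key, ka)
    ib <- match(key, kb)
    va <- if (!is.na(ia)) set_a[ia, ] else NULL
    vb <- if (!is.na(ib)) set_b[ib, ] else NULL
    if (!is.null(va) && !is.null(vb)) {
      if (va$type == vb$type && va$ref_allele == vb$ref_allele &&
          va$alt_allele == vb$alt_allele) {
        shared_idx <- c(shared_idx, ia)
        next
      }
      category <- "conflicting"
    } else category <- if (is.null(vb)) "a_only" else "b_only"
    anyv <- if (is.null(va)) vb else va
    is_ins <- substr(key, 1, 1) == "i"
    refall <- if (is_ins) "-" else anyv$ref_allele
    rows[[length(rows) + 1]] <- data.frame(
      position = anyv$position,
      site = if (is_ins) "anchor" else "point",
      category = category,
      type_a = if (is.null(va)) NA_character_ else va$type,
      type_b = if (is.null(vb)) NA_character_ else vb$type,
      ref_allele = refall,
      allele_a = if (is.null(va)) refall else va$alt_allele,
      allele_b = if (is.null(vb)) refall else vb$alt_allele,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(position = integer(0), site = character(0),
                         category = character(0), type_a = character(0),
                         type_b = character(0), ref_allele = character(0),
                         allele_a = character(0), allele_b = character(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shared") <- set_a[shared_idx, , drop = FALSE]
  out
}

#' Summarize contigs into site evidence
#'
#' Aligns one source's contigs to the reference and converts each placement
#' into (i) the variant calls it implies and (ii) the reference intervals it
#' covers, the form consumed by [gather_evidence()].
#'
#' @param contigs Contig data.frame.
#' @param ref The reference.
#' @param ... Passed to [align_contigs()].
#' @return `list(variants, covered)` where `covered` is a logical vector
#'   over reference positions.
#' @export
contig_evidence <- function(contigs, ref, ...) {
  refseq <- as_sequence(ref)
  L <- nchar(refseq)
  covered <- logical(L)
  vars <- empty_variants()
  if (nrow(contigs) > 0) {
    al <- align_contigs(contigs, refseq, ...)
    for (i in seq_len(nrow(al))) {
      covered[al$ref_start[i]:al$ref_end[i]] <- TRUE
      v <- variants_from_cigar(al$cigar[i], refseq, al$oriented[i],
                               ref_start = al$ref_start[i],
                               q_start = al$lead_unaligned[i] + 1L)
      vars <- rbind(vars, v[, names(empty_variants())])
    }
  }
  if (nrow(vars)) {
    vars <- normalize_variants(vars, refseq)
    vars <- vars[!duplicated(site_key(vars)), , drop = FALSE]
  }
  list(variants = vars, covered = covered)
}

#' Gather evidence for discrepancy records
#'
#' For every record, reads the allele implied by each de novo contig source
#' at the site (the reference allele when the site is covered but no
#' variant is called; `NA` when no contig covers the site), computes the
#' homopolymer context from the reference, and sets a mapping-ambiguity
#' flag when, in a +/- `window` bp neighbourhood, more than
#' `ambiguity_fraction` of covering reads carry at least
#' `ambiguity_mismatches` mismatches or were randomly placed multimappers.
#'
#' @param records Discrepancy records from [diff_variant_sets()].
#' @param contig_sources Named list of [contig_evidence()] results.
#' @param ref The reference.
#' @param alignments Optional list of alignment data.frames (per platform,
#'   as from [map_reads()]) used for the ambiguity flag.
#' @param window,ambiguity_mismatches,ambiguity_fraction Ambiguity
#'   thresholds.
#' @return A data.frame (one row per record): list-column `contig_alleles`
#'   (named character per source), `mapping_ambiguity`, `hp_base`,
#'   `hp_class`, `hp_run_length`.
#' @export
gather_evidence <- function(records, contig_sources, ref,
                            alignments = NULL, window = 25,
                            ambiguity_mismatches = 3,
                            ambiguity_fraction = 0.2) {
  refseq <- as_sequence(ref)
  n <- nrow(records)
  contig_alleles <- vector("list", n)
  ambig <- logical(n)
  hp_base <- hp_class <- character(n)
  hp_len <- integer(n)
  runs <- homopolymer_runs(refseq)
  src_keys <- lapply(contig_sources, function(sv) site_key(sv$variants))
  for (i in seq_len(n)) {
    pos <- records$position[i]
    key <- paste0(ifelse(records$site[i] == "anchor", "i", "p"), pos)
    refall <- records$ref_allele[i]
    alle <- vapply(seq_along(contig_sources), function(s) {
      sv <- contig_sources[[s]]
      hit <- match(key, src_keys[[s]])
      if (!is.na(hit)) return(sv$variants$alt_allele[hit])
      cov_at <- max(1, min(pos, length(sv$covered)))
      if (isTRUE(sv$covered[cov_at])) refall else NA_character_
    }, character(1))
    names(alle) <- names(contig_sources)
    contig_alleles[[i]] <- alle
    # homopolymer context: the run at/adjacent to the site
    focus <- records[i, ]
    vlike <- data.frame(position = pos,
                        type = if (focus$site == "anchor") "ins" else
                          if (focus$allele_b == "-" || focus$allele_a == "-") "del"
                          else "SNP",
                        ref_allele = if (focus$site == "anchor") "-" else refall,
                        alt_allele = if (focus$site == "anchor") {
                          av <- c(focus$allele_a, focus$allele_b)
                          av <- av[av != "-"]
                          if (length(av)) av[1] else "A"
                        } else "-",
                        stringsAsFactors = FALSE)
    ann <- annotate_homopolymer(vlike, refseq)
    hp_base[i] <- ann$hp_base
    hp_class[i] <- ann$hp_class
    hp_len[i] <- ann$hp_run_length
    if (!is.null(alignments)) {
      lo <- pos - window; hi <- pos + window
      fr <- vapply(alignments, function(al) {
        cov <- al$start <= hi & al$end >= lo
        if (!any(cov)) return(0)
        mean(al$mismatches[cov] >= ambiguity_mismatches | al$multimap[cov])
      }, numeric(1))
      ambig[i] <- any(fr > ambiguity_fraction)
    }
  }
  out <- data.frame(mapping_ambiguity = ambig, hp_base = hp_base,
                    hp_class = hp_class, hp_run_length = hp_len,
                    stringsAsFactors = FALSE)
  out$contig_alleles <- contig_alleles
  out
}

#' Resolve discrepancies by evidence rules
#'
#' Rules are applied in a fixed order; the first match decides:
#' \describe{
#'   \item{R1 (mapping artifact)}{every covering contig source carries the
#'     reference allele and the site is mapping-ambiguous: resolve to the
#'     reference.}
#'   \item{R2 (contig-supported variant)}{all contig sources cover the site
#'     and agree on one non-reference allele: adopt it (covers long
#'     insertions missed or mis-called by mapping).}
#'   \item{R3 (homopolymer read error)}{a single-platform indel in a run of
#'     length >= 2 whose covering contigs carry the reference allele:
#'     resolve to the reference.}
#'   \item{R4 (long-homopolymer ambiguity)}{an indel in a run of length >=
#'     `long_run` whose contig sources disagree among themselves:
#'     unresolved.}
#'   \item{R5 (default)}{covering contigs agree with exactly one platform:
#'     adopt that platform's allele; otherwise unresolved.}
#' }
#' Unresolved records default to the reference allele and are flagged
#' `uncertain`. Any resolution other than `unresolved` requires at least
#' one covering contig source.
#'
#' @param records Discrepancy records from [diff_variant_sets()].
#' @param evidence Evidence rows from [gather_evidence()] (or constructed
#'   directly, e.g. from a curated table).
#' @param long_run Run-length threshold for R4.
#' @return `records` with columns `resolution` (`reference`, `adopt_contig`,
#'   `adopt_a`, `adopt_b`, `unresolved`), `rule`, `resolved_allele`,
#'   `uncertain` added.
#' @export
resolve_discrepancies <- function(records, evidence, long_run = 8) {
  n <- nrow(records)
  stopifnot(nrow(evidence) == n)
  resolution <- character(n)
  rule <- character(n)
  resolved <- character(n)
  uncertain <- logical(n)
  for (i in seq_len(n)) {
    refall <- records$ref_allele[i]
    alle <- evidence$contig_alleles[[i]]
    present <- alle[!is.na(alle)]
    n_src <- length(alle)
    all_ref <- length(present) > 0 && all(present == refall)
    agree <- length(present) > 0 && length(unique(present)) == 1
    is_indel <- records$site[i] == "anchor" ||
      any(c(records$type_a[i], records$type_b[i]) %in% "del", na.rm = TRUE) ||
      records$allele_a[i] == "-" || records$allele_b[i] == "-"
    single <- records$category[i] %in% c("a_only", "b_only")
    hp <- evidence$hp_run_length[i]
    if (all_ref && evidence$mapping_ambiguity[i]) {
      resolution[i] <- "reference"; rule[i] <- "R1"; resolved[i] <- refall
    } else if (length(present) == n_src && agree && present[1] != refall) {
      resolution[i] <- "adopt_contig"; rule[i] <- "R2"; resolved[i] <- present[1]
    } else if (single && is_indel && hp >= 2 && all_ref) {
      resolution[i] <- "reference"; rule[i] <- "R3"; resolved[i] <- refall
    } else if (is_indel && hp >= long_run && length(present) >= 2 && !agree) {
      resolution[i] <- "unresolved"; rule[i] <- "R4"
      resolved[i] <- refall; uncertain[i] <- TRUE
    } else if (agree) {
      match_a <- present[1] == records$allele_a[i]
      match_b <- present[1] == records$allele_b[i]
      if (match_a && !match_b) {
        resolution[i] <- "adopt_a"; rule[i] <- "R5"; resolved[i] <- records$allele_a[i]
      } else if (match_b && !match_a) {
        resolution[i] <- "adopt_b"; rule[i] <- "R5"; resolved[i] <- records$allele_b[i]
      } else {
        resolution[i] <- "unresolved"; rule[i] <- "R5"
        resolved[i] <- refall; uncertain[i] <- TRUE
      }
    } else {
      resolution[i] <- "unresolved"; rule[i] <- "R5"
      resolved[i] <- refall; uncertain[i] <- TRUE
    }
  }
  records$resolution <- resolution
  records$rule <- rule
  records$resolved_allele <- resolved
  records$uncertain <- uncertain
  records
}

#' Build the amended consensus
#'
#' Applies the shared variants plus every resolved non-reference allele to
#' the reference, right-to-left so coordinates stay valid. Unresolved
#' records keep the reference allele (flagged upstream). Overlapping edits
#' raise an error listing the collision.
#'
#' @param ref The reference.
#' @param resolved Resolved records from [resolve_discrepancies()].
#' @param shared Data.frame of variants identical in both platforms.
#' @return `list(sequence, edits, length_change)`.
#' @export
amend_consensus <- function(ref, resolved, shared = empty_variants()) {
  refseq <- as_sequence(ref)
  edits <- list()
  if (nrow(shared) > 0) {
    s <- shared
    s$source <- "shared"
    edits[[1]] <- s[, c("position", "type", "ref_allele", "alt_allele", "source")]
  }
  if (nrow(resolved) > 0) {
    adopt <- resolved[resolved$resolved_allele != resolved$ref_allele, , drop = FALSE]
    if (nrow(adopt) > 0) {
      e <- data.frame(position = adopt$position,
                      type = ifelse(adopt$site == "anchor", "ins",
                                    ifelse(adopt$resolved_allele == "-", "del", "sub")),
                      ref_allele = adopt$ref_allele,
                      alt_allele = adopt$resolved_allele,
                      source = paste0("resolved:", adopt$rule),
                      stringsAsFactors = FALSE)
      e$type[e$type == "sub"] <- ifelse(nchar(e$ref_allele[e$type == "sub"]) == 1 &
                                          nchar(e$alt_allele[e$type == "sub"]) == 1,
                                        "SNP", "MNV")
      edits[[length(edits) + 1]] <- e
    }
  }
  if (length(edits) == 0)
    return(list(sequence = refseq, edits = empty_variants(), length_change = 0L))
  ed <- do.call(rbind, edits)
  # overlap check on reference footprints
  foot_s <- ifelse(ed$type == "ins", ed$position + 0.25, ed$position)
  foot_e <- ifelse(ed$type == "ins", ed$position + 0.75,
                   ed$position + nchar(ed$ref_allele) - 1)
  ord <- order(foot_s)
  if (any(foot_s[ord][-1] <= foot_e[ord][-length(ord)]))
    cpb_error(sprintf(
      "overlapping edits at reference position %d",
      ed$position[ord][which(foot_s[ord][-1] <= foot_e[ord][-length(ord)])[1] + 1]),
      "cpb_conflict_error")
  # MNV/SNP edits may replace with a different-length allele (composite
  # contig-derived alleles); apply generically
  s <- refseq
  ed2 <- ed[order(-(ed$position + 0.5 * (ed$type == "ins"))), , drop = FALSE]
  for (i in seq_len(nrow(ed2))) {
    p <- ed2$position[i]
    alt <- if (ed2$alt_allele[i] == "-") "" else ed2$alt_allele[i]
    if (ed2$type[i] == "ins") {
      s <- paste0(substr(s, 1, p), alt, substr(s, p + 1, nchar(s)))
    } else {
      l <- nchar(ed2$ref_allele[i])
      have <- substr(s, p, p + l - 1)
      if (have != ed2$ref_allele[i])
        cpb_error(sprintf(
          "edit at %d expects reference allele '%s' but found '%s'",
          p, ed2$ref_allele[i], have), "cpb_integrity_error")
      s <- paste0(substr(s, 1, p - 1), alt, substr(s, p + l, nchar(s)))
    }
  }
  list(sequence = s, edits = ed[order(ed$position), , drop = FALSE],
       length_change = nchar(s) - nchar(refseq))
}

#' Validate an amended consensus by remapping
#'
#' Maps reads to the amended sequence, extracts a majority-vote consensus,
#' and reports every site where that consensus differs from the amended
#' sequence (ideally only unresolved long-homopolymer sites remain).
#'
#' @param amended Amended sequence (string or [amend_consensus()] result).
#' @param reads A [read_set()].
#' @param params [mapping_params()].
#' @param seed Seed for multimap placement.
#' @return A data.frame of residual differences (variant table layout).
#' @export
validate_by_remap <- function(amended, reads, params = mapping_params(),
                              seed = 1L) {
  seqa <- if (is.list(amended)) amended$sequence else as_sequence(amended)
  if (length(reads) == 0) {
    warning("no reads supplied; remap validation skipped")
    return(empty_variants())
  }
  mp <- map_reads(reads, seqa, params, seed = seed)
  pp <- build_pileup(mp$alignments, seqa)
  cons <- call_consensus(pp)
  al <- align_consensus(cons$sequence, seqa)
  extract_variants(al)
}

#' Load the bundled cross-platform discrepancy case study
#'
#' The package ships a worked example of 20 cross-platform discrepancies
#' from a wild rice chloroplast barcoding comparison (short-read
#' sequencing-by-synthesis vs semiconductor long single reads), together
#' with curated per-site evidence: the alleles observed in de novo contigs
#' from two assembly sources, a mapping-ambiguity flag, and the
#' homopolymer context. The expected most-probable allele per site is
#' included for checking.
#'
#' @return `list(table, set_a, set_b, evidence, expected)` where `set_a`
#'   and `set_b` are the per-platform variant sets implied by the table.
#' @export
load_case_study <- function() {
  dir <- system.file("extdata", package = "cpbarcode")
  tbl <- read_variant_table(file.path(dir, "table3.tsv"))
  ev <- read.delim(file.path(dir, "table3_evidence.tsv"), sep = "\t",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  derive_set <- function(allele_col, type_col) {
    has <- tbl[[allele_col]] != tbl$ref_allele
    v <- tbl[has, , drop = FALSE]
    data.frame(position = v$position, type = v[[type_col]],
               ref_allele = v$ref_allele, alt_allele = v[[allele_col]],
               stringsAsFactors = FALSE)
  }
  # per-platform types: split slash-combined tokens (a/b order)
  split_type <- function(x, side) {
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(p) if (length(p) == 2) p[side] else p[1], character(1))
  }
  tbl$type_a <- split_type(tbl$type, 1)
  tbl$type_b <- split_type(tbl$type, 2)
  set_a <- derive_set("allele_a", "type_a")
  set_b <- derive_set("allele_b", "type_b")
  evidence <- data.frame(
    position = as.integer(ev$position),
    mapping_ambiguity = as.logical(ev$mapping_ambiguity),
    hp_base = ev$hp_base, hp_class = ev$hp_class,
    hp_run_length = as.integer(ev$hp_run_length), stringsAsFactors = FALSE)
  evidence$contig_alleles <- lapply(seq_len(nrow(ev)), function(i)
    c(source_1 = normalize_allele(ev$contig_source_1[i]),
      source_2 = normalize_allele(ev$contig_source_2[i])))
  # absent is encoded as the literal token "absent"
  evidence$contig_alleles <- lapply(evidence$contig_alleles, function(x) {
    x[x == "ABSENT"] <- NA_character_
    x
  })
  list(table = tbl, set_a = set_a, set_b = set_b, evidence = evidence,
       expected = normalize_allele(tbl$most_probable))
}
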