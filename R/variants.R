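# Variant extraction and classification against a reference, homopolymer
# context annotation, and the indel bias summaries.

parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("([0-9]+)([=XID])", cigar))[[1]]
  data.frame(len = as.integer(sub("[=XID]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

#' Fraction of G+C bases
#'
#' @param seq DNA string (or [plastome()]).
#' @return `(#G + #C) / length`.
#' @export
gc_content <- function(seq) {
  s <- as_sequence(seq)
  if (nchar(s) == 0) cpb_error("empty sequence", "cpb_parameter_error")
  gc <- nchar(gsub("[^GCgc]", "", s))
  gc / nchar(s)
}

#' Table of maximal homopolymer runs
#'
#' @param seq DNA string (or [plastome()]).
#' @return A data.frame with columns `start`, `end`, `len`, `base`, `class`
#'   (`"AT"` or `"GC"`), one row per maximal run (including length-1 runs).
#' @export
homopolymer_runs <- function(seq) {
  s <- as_sequence(seq)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, len = r$lengths,
             base = r$values,
             class = ifelse(r$values %in% c("A", "T"), "AT",
                            ifelse(r$values %in% c("C", "G"), "GC", NA)),
             stringsAsFactors = FALSE)
}

#' Census of homopolymer run lengths
#'
#' Counts maximal runs only; under the `"GC"` filter, runs of C and runs of
#' G are both counted (likewise A and T under `"AT"`).
#'
#' @param seq DNA string (or [plastome()]).
#' @param base_filter `NULL` (all bases), `"AT"`, or `"GC"`.
#' @param min_length Minimum run length to report.
#' @return Named integer vector mapping run length to count.
#' @export
homopolymer_census <- function(seq, base_filter = NULL, min_length = 1) {
  runs <- homopolymer_runs(seq)
  if (!is.null(base_filter)) {
    base_filter <- match.arg(base_filter, c("AT", "GC"))
    runs <- runs[!is.na(runs$class) & runs$class == base_filter, , drop = FALSE]
  }
  runs <- runs[runs$len >= min_length, , drop = FALSE]
  tab <- table(runs$len)
  setNames(as.integer(tab), names(tab))
}

#' Apply a variant table to a sequence
#'
#' Edits are applied right-to-left (descending position) so coordinates stay
#' valid; each edit's `ref_allele` is checked against the sequence first.
#' Insertions are anchored between `position` and `position + 1`.
#'
#' @param seq DNA string (or [plastome()]).
#' @param variants Variant data.frame with columns `position`, `type`,
#'   `ref_allele`, `alt_allele`.
#' @return The edited sequence string.
#' @export
apply_variants <- function(seq, variants) {
  s <- as_sequence(seq)
  if (nrow(variants) == 0) return(s)
  eff <- variants$position + 0.5 * (variants$type == "ins")
  v <- variants[order(-eff), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    if (v$type[i] == "ins") {
      s <- paste0(substr(s, 1, p), v$alt_allele[i], substr(s, p + 1, nchar(s)))
    } else {
      l <- nchar(v$ref_allele[i])
      have <- substr(s, p, p + l - 1)
      if (have != v$ref_allele[i])
        cpb_error(sprintf(
          "variant at %d expects reference allele '%s' but sequence has '%s'",
          p, v$ref_allele[i], have), "cpb_integrity_error")
      alt <- if (v$alt_allele[i] == "-") "" else v$alt_allele[i]
      s <- paste0(substr(s, 1, p - 1), alt, substr(s, p + l, nchar(s)))
    }
  }
  s
}

#' Left-normalize indels
#'
#' Indels inside repeats are shifted to their leftmost equivalent position,
#' the convention required for cross-platform position matching.
#'
#' @param variants Variant data.frame.
#' @param ref Reference sequence the positions refer to.
#' @return The data.frame with normalized `position` and alleles.
#' @export
normalize_variants <- function(variants, ref) {
  s <- as_sequence(ref)
  if (nrow(variants) == 0) return(variants)
  variants$position <- as.integer(variants$position)
  for (i in seq_len(nrow(variants))) {
    type <- variants$type[i]
    if (type == "del") {
      p <- variants$position[i]
      l <- nchar(variants$ref_allele[i])
      while (p > 1 && substr(s, p - 1, p - 1) == substr(s, p + l - 1, p + l - 1)) {
        p <- p - 1L
      }
      variants$position[i] <- p
      variants$ref_allele[i] <- substr(s, p, p + l - 1)
    } else if (type == "ins") {
      p <- variants$position[i]
      a <- variants$alt_allele[i]
      l <- nchar(a)
      while (p >= 1 && substr(s, p, p) == substr(a, l, l)) {
        a <- paste0(substr(s, p, p), substr(a, 1, l - 1))
        p <- p - 1L
      }
      variants$position[i] <- p
      variants$alt_allele[i] <- a
    }
  }
  variants
}

#' Globally align a consensus to the reference
#'
#' Unit mismatch cost with affine gaps (open 2, extend 1); deterministic.
#' Chloroplast-scale inputs are handled by anchor decomposition: unique
#' shared 20-mers are chained colinearly and exact dynamic programming is
#' run between anchors.
#'
#' @param consensus Consensus sequence (string or `cpb_consensus`).
#' @param ref A [plastome()] or reference string.
#' @param anchor_k Anchor k-mer length.
#' @param max_length_disparity Guard: error when the sequence lengths differ
#'   by more than this fraction (catches wrong inputs).
#' @return A `cpb_pairwise`: `cigar` (extended, query-vs-reference), `cost`,
#'   `query`, `ref`.
#' @export
align_consensus <- function(consensus, ref, anchor_k = 20,
                            max_length_disparity = 0.2) {
  q <- if (inherits(consensus, "cpb_consensus")) consensus$sequence
       else as_sequence(consensus)
  r <- as_sequence(ref)
  if (abs(nchar(q) - nchar(r)) > max_length_disparity * max(nchar(q), nchar(r)))
    cpb_error(sprintf(
      "sequence lengths differ by more than %.0f%% (%d vs %d); wrong input?",
      100 * max_length_disparity, nchar(q), nchar(r)), "cpb_parameter_error")
  al <- cpp_anchor_align(q, r, anchor_k, 1L, 2L, 1L, FALSE)
  structure(list(cigar = al$cigar, cost = al$cost, query = q, ref = r),
            class = "cpb_pairwise")
}

variants_from_cigar <- function(cigar, refseq, qseq, ref_start = 1L,
                                q_start = 1L) {
  ops <- parse_cigar(cigar)
  rows <- list()
  r <- as.integer(ref_start)
  q <- as.integer(q_start)
  for (i in seq_len(nrow(ops))) {
    l <- ops$len[i]
    op <- ops$op[i]
    if (op == "=") { r <- r + l; q <- q + l }
    else if (op == "X") {
      rows[[length(rows) + 1]] <- data.frame(
        position = r, type = if (l == 1) "SNP" else "MNV",
        ref_allele = substr(refseq, r, r + l - 1),
        alt_allele = substr(qseq, q, q + l - 1), stringsAsFactors = FALSE)
      r <- r + l; q <- q + l
    } else if (op == "D") {
      rows[[length(rows) + 1]] <- data.frame(
        position = r, type = "del",
        ref_allele = substr(refseq, r, r + l - 1),
        alt_allele = "-", stringsAsFactors = FALSE)
      r <- r + l
    } else if (op == "I") {
      rows[[length(rows) + 1]] <- data.frame(
        position = r - 1L, type = "ins", ref_allele = "-",
        alt_allele = substr(qseq, q, q + l - 1), stringsAsFactors = FALSE)
      q <- q + l
    }
  }
  if (length(rows) == 0) return(empty_variants())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Extract variants from a pairwise alignment
#'
#' Maximal runs of adjacent substituted columns merge into one SNP (length
#' 1) or MNV (length >= 2); maximal gap runs become one insertion or
#' deletion. Indels are left-normalized; the result is sorted by position
#' and SNPs carry a `substitution_class` column.
#'
#' @param alignment A `cpb_pairwise` from [align_consensus()].
#' @return A variant data.frame.
#' @export
extract_variants <- function(alignment) {
  stopifnot(inherits(alignment, "cpb_pairwise"))
  v <- variants_from_cigar(alignment$cigar, alignment$ref, alignment$query)
  v <- normalize_variants(v, alignment$ref)
  v <- v[order(v$position, v$type), , drop = FALSE]
  rownames(v) <- NULL
  v$position <- as.integer(v$position)
  v$substitution_class <- ifelse(
    v$type == "SNP", classify_substitution(v$ref_allele, v$alt_allele),
    NA_character_)
  v
}

#' Classify a base substitution
#'
#' Transitions are exactly A<->G and C<->T; everything else is a
#' transversion.
#'
#' @param ref_base,alt_base Single bases (vectorized).
#' @return `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(ref_base, alt_base) {
  if (any(ref_base == alt_base))
    cpb_error("identical bases cannot be classified", "cpb_parameter_error")
  purine <- c("A", "G")
  ifelse((ref_base %in% purine) == (alt_base %in% purine),
         "transition", "transversion")
}

#' Annotate variants with homopolymer context
#'
#' For a deletion the context is the maximal run containing the deleted
#' base; for an insertion, the maximal run of the inserted base touching
#' the anchor (run length 1 when no matching neighbour exists); for a
#' substitution, the run containing the position. Multi-base events with
#' mixed bases are annotated with the first base's context and flagged.
#'
#' @param variants Variant data.frame.
#' @param ref The reference sequence.
#' @return The data.frame with columns `hp_base`, `hp_class`,
#'   `hp_run_length`, `hp_start`, `hp_end`, `hp_mixed` added.
#' @export
annotate_homopolymer <- function(variants, ref) {
  s <- as_sequence(ref)
  runs <- homopolymer_runs(s)
  n <- nrow(variants)
  hp_base <- hp_class <- character(n)
  hp_len <- hp_start <- hp_end <- integer(n)
  hp_mixed <- logical(n)
  run_at <- function(pos) {
    idx <- findInterval(pos, runs$start)
    runs[idx, , drop = FALSE]
  }
  for (i in seq_len(n)) {
    type <- variants$type[i]
    p <- variants$position[i]
    if (type == "ins") {
      allele <- variants$alt_allele[i]
      base <- substr(allele, 1, 1)
      hp_mixed[i] <- nchar(allele) > 1 &&
        length(unique(strsplit(allele, "")[[1]])) > 1
      at <- if (p >= 1 && substr(s, p, p) == base) p
            else if (p + 1 <= nchar(s) && substr(s, p + 1, p + 1) == base) p + 1
            else NA_integer_
      if (is.na(at)) {
        hp_base[i] <- base
        hp_class[i] <- if (base %in% c("A", "T")) "AT" else "GC"
        hp_len[i] <- 1L; hp_start[i] <- p; hp_end[i] <- p + 1L
        next
      }
      r <- run_at(at)
    } else {
      allele <- variants$ref_allele[i]
      base <- substr(allele, 1, 1)
      hp_mixed[i] <- nchar(allele) > 1 &&
        length(unique(strsplit(allele, "")[[1]])) > 1
      r <- run_at(p)
    }
    hp_base[i] <- r$base
    hp_class[i] <- r$class
    hp_len[i] <- r$len
    hp_start[i] <- r$start
    hp_end[i] <- r$end
  }
  variants$hp_base <- hp_base
  variants$hp_class <- hp_class
  variants$hp_run_length <- hp_len
  variants$hp_start <- hp_start
  variants$hp_end <- hp_end
  variants$hp_mixed <- hp_mixed
  variants
}

#' Summarize homopolymer indel bias
#'
#' Indels are deduplicated by (position, type, alleles) before counting,
#' then tallied by indel type, homopolymer run length, and base class.
#'
#' @param variants Variants annotated by [annotate_homopolymer()].
#' @return A `cpb_bias`: `by` (data.frame of counts by type, run length and
#'   class), `totals` (named counts by class), `n` (total indels counted).
#' @export
summarize_bias <- function(variants) {
  v <- variants[variants$type %in% c("ins", "del"), , drop = FALSE]
  if (nrow(v) > 0 &&
      (!"hp_run_length" %in% names(v) || anyNA(v$hp_run_length)))
    cpb_error("variants must be annotated with annotate_homopolymer() first",
              "cpb_parameter_error")
  key <- paste(v$position, v$type, v$ref_allele, v$alt_allele)
  v <- v[!duplicated(key), , drop = FALSE]
  if (nrow(v) == 0) {
    return(structure(list(by = data.frame(type = character(0),
                                          run_length = integer(0),
                                          class = character(0),
                                          n = integer(0),
                                          stringsAsFactors = FALSE),
                          totals = c(AT = 0L, GC = 0L), n = 0L),
                     class = "cpb_bias"))
  }
  by <- aggregate(list(n = seq_len(nrow(v))),
                  by = list(type = v$type, run_length = v$hp_run_length,
                            class = v$hp_class),
                  FUN = length)
  by <- by[order(by$type, by$class, by$run_length), , drop = FALSE]
  rownames(by) <- NULL
  totals <- c(AT = sum(v$hp_class == "AT"), GC = sum(v$hp_class == "GC"))
  structure(list(by = by, totals = totals, n = nrow(v)), class = "cpb_bias")
}

#' @export
print.cpb_bias <- function(x, ...) {
  cat(sprintf("<indel bias summary: %d indels (GC %d, AT %d)>\n",
              x$n, x$totals["GC"], x$totals["AT"]))
  if (nrow(x$by)) print(x$by)
  invisible(x)
}
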