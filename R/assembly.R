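# De novo assembly into contigs, contig polishing, scaffolding against a
# reference (allowing non-unique matches for the inverted repeats), and
# joining into a de-novo consensus.

#' Assembly parameters
#'
#' @param k Word (k-mer) size: an odd integer in `[15, 31]`, or `"auto"`
#'   (`round(log4(total input bases))`, clipped to `[15, 31]` and forced
#'   odd).
#' @param bubble_size Maximum bubble path length (bases) resolved by
#'   coverage-weighted majority.
#' @param min_contig_length Contigs shorter than this are discarded; must be
#'   at least `k`.
#' @param cov_floor Minimum k-mer multiplicity (singleton k-mers are
#'   dropped as likely errors).
#' @param reference_guided When assembling with a reference, branch ties are
#'   resolved toward the reference allele (the contigs remain read-derived).
#' @param rounds Tip-clipping / bubble-popping rounds.
#' @return A `cpb_assembly_params` list.
#' @export
assembly_params <- function(k = "auto", bubble_size = 50,
                            min_contig_length = 200, cov_floor = 2,
                            reference_guided = FALSE, rounds = 3) {
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k %% 2 == 0) cpb_error("k must be odd", "cpb_parameter_error")
    if (k < 15 || k > 31)
      cpb_error("k must lie in [15, 31]", "cpb_parameter_error")
    if (min_contig_length < k)
      cpb_error("min_contig_length must be >= k", "cpb_parameter_error")
  }
  structure(list(k = k, bubble_size = as.integer(bubble_size),
                 min_contig_length = as.integer(min_contig_length),
                 cov_floor = as.integer(cov_floor),
                 reference_guided = reference_guided,
                 rounds = as.integer(rounds)),
            class = "cpb_assembly_params")
}

auto_k <- function(total_bases) {
  k <- round(log(max(total_bases, 2), base = 4))
  k <- min(max(k, 15L), 31L)
  if (k %% 2 == 0) k <- k + 1L
  as.integer(k)
}

#' Assemble reads into contigs
#'
#' De Bruijn graph assembly: k-mers below the coverage floor are dropped,
#' short dead-end tips (< 2k bases) are clipped, bubbles narrower than
#' `bubble_size` are resolved by coverage-weighted majority (toward the
#' reference allele in reference-guided mode), and maximal unbranched paths
#' are emitted as contigs.
#'
#' @param reads A [read_set()].
#' @param params [assembly_params()].
#' @param reference Optional [plastome()] used only when
#'   `params$reference_guided`.
#' @return A data.frame of contigs (`id`, `seq`, `mean_depth`), longest
#'   first. Empty (with a message) when no k-mer passes the coverage floor.
#' @export
assemble <- function(reads, params = assembly_params(), reference = NULL) {
  stopifnot(inherits(reads, "cpb_reads"))
  k <- if (identical(params$k, "auto")) auto_k(sum(nchar(reads$bases)))
       else params$k
  guide <- if (params$reference_guided && !is.null(reference))
    as_sequence(reference) else character(0)
  ctg <- cpp_assemble(reads$bases, k, params$bubble_size,
                      params$min_contig_length, params$cov_floor, guide,
                      params$rounds)
  if (nrow(ctg) == 0) {
    message("assembly produced no contigs (no k-mer passed the coverage floor ",
            "or all paths were shorter than min_contig_length)")
    return(data.frame(id = character(0), seq = character(0),
                      mean_depth = numeric(0), stringsAsFactors = FALSE))
  }
  ord <- order(-nchar(ctg$seq))
  out <- data.frame(id = sprintf("contig_%04d", seq_along(ord)),
                    seq = ctg$seq[ord], mean_depth = ctg$depth[ord],
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  out
}

#' Polish contigs by remapping reads
#'
#' Reads are mapped back to the contigs with the same cost model used for
#' reference mapping and each contig is replaced by its majority-vote
#' consensus, iterating to convergence (at most `iterations` rounds).
#' Contigs attracting no reads are returned unchanged and flagged.
#'
#' @param contigs Contig data.frame from [assemble()].
#' @param reads The read set to map back.
#' @param params [mapping_params()].
#' @param iterations Maximum polish rounds.
#' @param seed Seed for multimap placement.
#' @return The polished contig data.frame, with a logical `unpolished`
#'   column flagging contigs that attracted no reads.
#' @export
polish_contigs <- function(contigs, reads, params = mapping_params(),
                           iterations = 3, seed = 1L) {
  if (nrow(contigs) == 0) return(contigs)
  unpolished <- rep(FALSE, nrow(contigs))
  for (iter in seq_len(iterations)) {
    mp <- map_reads(reads, contigs$seq, params, seed = seed + iter)
    newseq <- contigs$seq
    for (ci in seq_len(nrow(contigs))) {
      al <- mp$alignments[mp$alignments$ref == ci, , drop = FALSE]
      if (nrow(al) == 0) { unpolished[ci] <- TRUE; next }
      pp <- build_pileup(al, contigs$seq[ci])
      cons <- call_consensus(pp)
      newseq[ci] <- cons$sequence
    }
    if (all(newseq == contigs$seq)) break
    contigs$seq <- newseq
  }
  contigs$unpolished <- unpolished
  contigs
}

#' Align contigs to a reference
#'
#' Anchor-based placement in the spirit of a maximal-exact-match aligner:
#' unique contig 20-mers are matched to the reference (up to 4 occurrences,
#' so both IR copies are found), clustered by diagonal, and each cluster is
#' refined with an anchored global alignment of the contig against the
#' projected reference window. With `allow_nonunique` a contig matching
#' both inverted-repeat copies yields two alignments.
#'
#' @param contigs Contig data.frame (`id`, `seq`).
#' @param ref A [plastome()] or reference string.
#' @param allow_nonunique Report all acceptable placements, not just the
#'   best one.
#' @param anchor_k Anchor k-mer length.
#' @param min_anchor_bases Anchoring floor: clusters whose anchors span
#'   fewer reference bases are ignored (unrelated contigs get no
#'   alignment).
#' @param min_identity Placements below this identity are discarded
#'   (spurious anchor clusters, e.g. short palindromic matches).
#' @return A data.frame of scaffold alignments: `contig_id`, `ref_start`,
#'   `ref_end`, `strand`, `query_coverage`, `percent_identity`,
#'   `aligned_length`, `unique`, `cigar`, `oriented` (contig sequence in
#'   reference orientation).
#' @export
align_contigs <- function(contigs, ref, allow_nonunique = TRUE,
                          anchor_k = 20, min_anchor_bases = 60,
                          min_identity = 0.8) {
  refseq <- as_sequence(ref)
  L <- nchar(refseq)
  out <- list()
  for (ci in seq_len(nrow(contigs))) {
    qlen <- nchar(contigs$seq[ci])
    placements <- list()
    for (strand in c(1L, -1L)) {
      q <- if (strand == 1L) contigs$seq[ci] else revcomp(contigs$seq[ci])
      hits <- cpp_anchor_hits(q, refseq, anchor_k)
      if (nrow(hits) == 0) next
      diag <- hits$rpos - hits$qpos
      ord <- order(diag)
      grp <- cumsum(c(1L, diff(diag[ord]) > 200L))
      for (g in unique(grp)) {
        idx <- ord[grp == g]
        span <- max(hits$rpos[idx]) + anchor_k - min(hits$rpos[idx])
        if (span < min_anchor_bases || length(idx) < 2) next
        ds <- min(diag[idx]); de <- max(diag[idx])
        ws <- max(1L, ds - 50L)
        we <- min(L, de + qlen + 50L)
        al <- cpp_anchor_align(q, substr(refseq, ws, we), anchor_k,
                               1L, 2L, 1L, TRUE)
        ops <- parse_cigar(al$cigar)
        cols_op <- rep(ops$op, ops$len)
        # clip to the well-matching core: a contig spanning an inverted
        # repeat carries flanking sequence foreign to the other IR copy;
        # trim each end up to the first/last clean run of 20 matches
        eq_runs <- rle(cols_op == "=")
        run_end <- cumsum(eq_runs$lengths)
        run_start <- run_end - eq_runs$lengths + 1L
        good <- which(eq_runs$values & eq_runs$lengths >= 20)
        if (length(good) == 0) next
        core_s <- run_start[good[1]]
        core_e <- run_end[good[length(good)]]
        clip_l <- if (core_s > 1) cols_op[1:(core_s - 1)] else character(0)
        clip_r <- if (core_e < length(cols_op))
          cols_op[(core_e + 1):length(cols_op)] else character(0)
        core_cols <- cols_op[core_s:core_e]
        q_l <- sum(clip_l %in% c("=", "X", "I"))
        r_l <- sum(clip_l %in% c("=", "X", "D"))
        q_r <- sum(clip_r %in% c("=", "X", "I"))
        r_core <- sum(core_cols %in% c("=", "X", "D"))
        rr <- rle(core_cols)
        core_cigar <- paste0(rr$lengths, rr$values, collapse = "")
        cols <- length(core_cols)
        matches <- sum(core_cols == "=")
        if (matches / cols < min_identity) next
        placements[[length(placements) + 1]] <- data.frame(
          contig_id = contigs$id[ci],
          ref_start = ws + al$b_start - 1L + r_l,
          ref_end = ws + al$b_start - 1L + r_l + r_core - 1L,
          strand = strand,
          query_coverage = (qlen - q_l - q_r) / qlen,
          percent_identity = matches / cols,
          aligned_length = cols, cigar = core_cigar,
          lead_unaligned = q_l,
          oriented = q, stringsAsFactors = FALSE)
      }
    }
    if (length(placements) == 0) next
    pl <- do.call(rbind, placements)
    # drop near-duplicate placements of the same region
    keep <- rep(TRUE, nrow(pl))
    if (nrow(pl) > 1) {
      ord <- order(-(pl$aligned_length * pl$percent_identity))
      pl <- pl[ord, , drop = FALSE]
      keep <- rep(TRUE, nrow(pl))
      for (i in seq_len(nrow(pl))[-1]) {
        for (j in seq_len(i - 1)) {
          if (!keep[j]) next
          ov <- min(pl$ref_end[i], pl$ref_end[j]) -
            max(pl$ref_start[i], pl$ref_start[j]) + 1
          if (ov > 0.8 * (pl$ref_end[i] - pl$ref_start[i] + 1)) {
            keep[i] <- FALSE; break
          }
        }
      }
    }
    pl <- pl[keep, , drop = FALSE]
    if (!allow_nonunique && nrow(pl) > 1)
      pl <- pl[1, , drop = FALSE]
    pl$unique <- nrow(pl) == 1
    out[[length(out) + 1]] <- pl
  }
  if (length(out) == 0)
    return(data.frame(contig_id = character(0), ref_start = integer(0),
                      ref_end = integer(0), strand = integer(0),
                      query_coverage = numeric(0), percent_identity = numeric(0),
                      aligned_length = integer(0), cigar = character(0),
                      lead_unaligned = integer(0), oriented = character(0),
                      unique = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# project reference positions to (oriented) query positions for one
# scaffold alignment row; returns an integer vector over ref_start..ref_end
ref_to_query_map <- function(aln) {
  ops <- parse_cigar(aln$cigar)
  span <- aln$ref_end - aln$ref_start + 1L
  qmap <- integer(span)
  r <- 0L
  q <- 0L
  for (i in seq_len(nrow(ops))) {
    l <- ops$len[i]; op <- ops$op[i]
    if (op == "=" || op == "X") {
      qmap[(r + 1):(r + l)] <- (q + 1):(q + l)
      r <- r + l; q <- q + l
    } else if (op == "D") {
      qmap[(r + 1):(r + l)] <- q       # deleted ref base -> last query base
      r <- r + l
    } else if (op == "I") {
      q <- q + l
    }
  }
  qmap
}

#' Join scaffolded contigs into a de novo consensus
#'
#' Placements are ranked by (aligned length, identity, query coverage)
#' descending and greedily tiled along the reference; adjacent tiles are
#' merged when their sequences overlap by at least `min_overlap` bases with
#' at least `overlap_identity` agreement. Any uncovered reference interval
#' aborts joining with a gap report; conflicting overlaps raise an error
#' naming the interval.
#'
#' @param alignments Scaffold alignments from [align_contigs()].
#' @param contigs The contig data.frame (for diagnostics; sequences are
#'   taken from the alignments, which carry reference-oriented copies).
#' @param ref The reference.
#' @param min_overlap Minimum overlap (bases) for merging adjacent tiles.
#' @param overlap_identity Minimum agreement within an overlap.
#' @param end_tolerance Uncovered stretches at the reference ends up to this
#'   length are treated as coverage erosion (the consensus simply starts or
#'   ends there), not as gaps.
#' @return A `cpb_join`: either `type = "consensus"` with `sequence` and the
#'   tile table, or `type = "gaps"` with a data.frame of uncovered
#'   intervals.
#' @export
join_contigs <- function(alignments, contigs, ref, min_overlap = 20,
                         overlap_identity = 0.95, end_tolerance = 150) {
  refseq <- as_sequence(ref)
  L <- nchar(refseq)
  if (nrow(alignments) == 0)
    return(structure(list(type = "gaps",
                          gaps = data.frame(start = 1L, end = L)),
                     class = "cpb_join"))
  ord <- order(-alignments$aligned_length, -alignments$percent_identity,
               -alignments$query_coverage)
  al <- alignments[ord, , drop = FALSE]
  covered <- logical(L)
  take <- logical(nrow(al))
  for (i in seq_len(nrow(al))) {
    iv <- al$ref_start[i]:al$ref_end[i]
    if (any(!covered[iv])) { take[i] <- TRUE; covered[iv] <- TRUE }
  }
  tiles <- al[take, , drop = FALSE]
  tiles <- tiles[order(tiles$ref_start), , drop = FALSE]
  if (any(!covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gaps <- data.frame(start = starts[!r$values], end = ends[!r$values])
    lead <- gaps$start == 1L & (gaps$end - gaps$start + 1) <= end_tolerance
    trail <- gaps$end == L & (gaps$end - gaps$start + 1) <= end_tolerance
    gaps <- gaps[!(lead | trail), , drop = FALSE]
    if (nrow(gaps) > 0)
      return(structure(list(type = "gaps", gaps = gaps, tiles = tiles),
                       class = "cpb_join"))
  }
  # merge tiles left to right
  qmaps <- lapply(seq_len(nrow(tiles)), function(i)
    ref_to_query_map(tiles[i, , drop = FALSE]))
  first_q <- tiles$lead_unaligned[1]
  pieces <- substr(tiles$oriented[1], first_q + 1,
                   first_q + max(qmaps[[1]]))
  prev_end <- tiles$ref_end[1]
  for (i in seq_len(nrow(tiles))[-1]) {
    s <- tiles$ref_start[i]
    if (s > prev_end + 1)
      cpb_error("internal: uncovered interval survived gap check",
                "cpb_integrity_error")
    if (prev_end >= tiles$ref_end[i]) next   # fully contained
    ov_len <- prev_end - s + 1L
    if (ov_len < min_overlap && ov_len < 1) ov_len <- 0L
    q0 <- tiles$lead_unaligned[i]
    qm <- qmaps[[i]]
    if (ov_len > 0) {
      j <- which(seq_len(nrow(tiles)) < i & tiles$ref_end >= s)
      j <- j[length(j)]
      prev_qm <- qmaps[[j]]
      prev_span <- (s - tiles$ref_start[j] + 1):(prev_end - tiles$ref_start[j] + 1)
      a <- substr(tiles$oriented[j],
                  tiles$lead_unaligned[j] + prev_qm[prev_span[1]],
                  tiles$lead_unaligned[j] + prev_qm[prev_span[length(prev_span)]])
      b <- substr(tiles$oriented[i], q0 + qm[1], q0 + qm[ov_len])
      agree <- overlap_agreement(a, b)
      if (ov_len >= min_overlap && agree < overlap_identity)
        cpb_error(sprintf(
          "conflicting overlap between %s and %s on reference [%d, %d] (agreement %.2f)",
          tiles$contig_id[j], tiles$contig_id[i], s, prev_end, agree),
          "cpb_conflict_error")
    }
    from <- q0 + (if (ov_len > 0) qm[ov_len] + 1L else qm[1])
    to <- q0 + max(qm)
    if (from <= to)
      pieces <- c(pieces, substr(tiles$oriented[i], from, to))
    prev_end <- tiles$ref_end[i]
  }
  structure(list(type = "consensus", sequence = paste(pieces, collapse = ""),
                 tiles = tiles), class = "cpb_join")
}

overlap_agreement <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    if (nchar(a) == 0) return(1)
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    return(mean(av == bv))
  }
  al <- cpp_anchor_align(a, b, 12L, 1L, 2L, 1L, FALSE)
  ops <- parse_cigar(al$cigar)
  sum(ops$len[ops$op == "="]) / sum(ops$len)
}

#' @export
print.cpb_join <- function(x, ...) {
  if (x$type == "consensus") {
    cat(sprintf("<de novo consensus: %d bp from %d tiles>\n",
                nchar(x$sequence), nrow(x$tiles)))
  } else {
    cat(sprintf("<gap report: %d uncovered interval(s)>\n", nrow(x$gaps)))
    print(x$gaps)
  }
  invisible(x)
}
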