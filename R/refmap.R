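# Reference mapping: seed-and-extend placement under an explicit cost model,
# pileup construction, and majority-vote consensus extraction.

#' Read-mapping parameters
#'
#' The cost model and acceptance thresholds used for read placement:
#' mismatch cost 2, insertion and deletion cost 3 per base, and acceptance
#' requires at least `length_fraction` of the read aligned (alignment is
#' end-to-end on the read, so this is always satisfied) and
#' `similarity_fraction` identity over aligned columns. Reads with several
#' equal-best placements (e.g. inside the inverted repeats) are either
#' placed at random (seeded) or discarded.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost Positive integer costs.
#' @param length_fraction,similarity_fraction Acceptance fractions in (0, 1].
#' @param multimap_policy `"random"` (seeded uniform choice among equal-best
#'   sites) or `"discard"`.
#' @param k Seed k-mer length (reads shorter than `k` are unmapped).
#' @param band Diagonal band half-width for the extension DP window.
#' @param seed_stride Spacing of seed k-mers along the read.
#' @param max_clusters Maximum candidate placements examined per read.
#' @return A `cpb_mapping_params` list.
#' @export
mapping_params <- function(mismatch_cost = 2, insertion_cost = 3,
                           deletion_cost = 3, length_fraction = 0.9,
                           similarity_fraction = 0.9,
                           multimap_policy = c("random", "discard"),
                           k = 15, band = 16, seed_stride = 7,
                           max_clusters = 16) {
  multimap_policy <- match.arg(multimap_policy)
  if (any(c(mismatch_cost, insertion_cost, deletion_cost) <= 0))
    cpb_error("alignment costs must be positive", "cpb_parameter_error")
  if (any(c(length_fraction, similarity_fraction) <= 0) ||
      any(c(length_fraction, similarity_fraction) > 1))
    cpb_error("acceptance fractions must be in (0, 1]", "cpb_parameter_error")
  structure(list(mismatch_cost = as.integer(mismatch_cost),
                 insertion_cost = as.integer(insertion_cost),
                 deletion_cost = as.integer(deletion_cost),
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction,
                 multimap_policy = multimap_policy, k = as.integer(k),
                 band = as.integer(band), seed_stride = as.integer(seed_stride),
                 max_clusters = as.integer(max_clusters)),
            class = "cpb_mapping_params")
}

map_batch <- function(bases, refs, params) {
  cpp_map_reads(bases, refs, params$k, params$band, params$mismatch_cost,
                params$insertion_cost, params$deletion_cost,
                params$length_fraction, params$similarity_fraction,
                params$seed_stride, params$max_clusters)
}

#' Map a single read
#'
#' Returns the minimum-cost placement of the read (end-to-end on the read,
#' both strands considered), with acceptance thresholds applied after
#' optimization. Equal-best placements are reported as `"multimapped"`.
#'
#' @param read A length-1 [read_set()] or a plain base string.
#' @param ref A [plastome()] or reference string(s).
#' @param params [mapping_params()].
#' @return `list(status, placements)` where `status` is one of `"mapped"`,
#'   `"multimapped"`, `"unmapped"`, `"too_short"`, and `placements` is a
#'   data.frame of the equal-best placements (1-based inclusive reference
#'   coordinates, cost, identity, extended-CIGAR `cigar`).
#' @export
map_read <- function(read, ref, params = mapping_params()) {
  bases <- if (inherits(read, "cpb_reads")) read$bases else as.character(read)
  stopifnot(length(bases) == 1)
  refs <- if (inherits(ref, "cpb_plastome")) ref$sequence else as.character(ref)
  res <- map_batch(bases, refs, params)
  status <- c("unmapped", "mapped", "multimapped", "too_short")[res$status + 1]
  plc <- res$placements
  plc$identity <- ifelse(plc$columns > 0, plc$matches / plc$columns, 0)
  list(status = status, placements = plc)
}

#' Map a read set to a reference
#'
#' Batch version of [map_read()]. Multimapped reads are resolved according
#' to `params$multimap_policy`; random placement is deterministic under
#' `seed`.
#'
#' @param reads A [read_set()].
#' @param ref A [plastome()], reference string, or character vector of
#'   target sequences (e.g. contigs for polishing).
#' @param params [mapping_params()].
#' @param seed Seed for random multimap placement.
#' @return `list(alignments, report)`. `alignments` is a data.frame with
#'   one row per placed read: `read` (index), `read_id`, `ref` (target
#'   index), `start`, `end`, `strand`, `cost`, `matches`, `mismatches`,
#'   `read_gaps`, `ref_gaps`, `columns`, `cigar`, `identity`, `multimap`,
#'   and `oriented` (read bases in reference orientation). `report` carries
#'   mapped/multimap/unmapped counts and the mapped fraction.
#' @export
map_reads <- function(reads, ref, params = mapping_params(), seed = 1L) {
  stopifnot(inherits(reads, "cpb_reads"))
  refs <- if (inherits(ref, "cpb_plastome")) ref$sequence else as.character(ref)
  n <- length(reads)
  if (n == 0) {
    return(list(alignments = empty_alignments(),
                report = list(total = 0L, mapped = 0L, multimapped = 0L,
                              unmapped = 0L, mapped_fraction = 0)))
  }
  res <- map_batch(reads$bases, refs, params)
  plc <- res$placements
  plc$identity <- ifelse(plc$columns > 0, plc$matches / plc$columns, 0)
  status <- res$status
  multi <- which(status == 2L)
  keep_rows <- which(plc$read %in% which(status == 1L))
  chosen <- plc[keep_rows, , drop = FALSE]
  chosen$multimap <- rep(FALSE, nrow(chosen))
  if (length(multi)) {
    if (params$multimap_policy == "random") {
      set.seed(seed)
      picked <- lapply(multi, function(rd) {
        rows <- which(plc$read == rd)
        plc[sample(rows, 1), , drop = FALSE]
      })
      picked <- do.call(rbind, picked)
      picked$multimap <- TRUE
      chosen <- rbind(chosen, picked)
    } # discard policy: drop them
  }
  chosen <- chosen[order(chosen$read), , drop = FALSE]
  chosen$read_id <- reads$id[chosen$read]
  chosen$oriented <- ifelse(chosen$strand == 1L, reads$bases[chosen$read],
                            revcomp(reads$bases[chosen$read]))
  rownames(chosen) <- NULL
  mapped <- sum(status == 1L) +
    if (params$multimap_policy == "random") length(multi) else 0L
  list(alignments = chosen,
       report = list(total = n, mapped = mapped,
                     multimapped = length(multi),
                     unmapped = sum(status == 0L) + sum(status == 3L),
                     mapped_fraction = mapped / n))
}

empty_alignments <- function() {
  data.frame(read = integer(0), ref = integer(0), start = integer(0),
             end = integer(0), strand = integer(0), cost = integer(0),
             matches = integer(0), mismatches = integer(0),
             read_gaps = integer(0), ref_gaps = integer(0),
             columns = integer(0), cigar = character(0),
             identity = numeric(0), multimap = logical(0),
             read_id = character(0), oriented = character(0),
             stringsAsFactors = FALSE)
}

#' Build a pileup from alignments
#'
#' Tallies every aligned base and deletion exactly once per reference
#' position; insertions are keyed by their anchor (between `pos` and
#' `pos + 1`). Also records, per anchor, how many reads span the junction
#' (only junction-spanning reads vote on insertions).
#'
#' @param alignments Alignment data.frame from [map_reads()] (rows for one
#'   target; use `ref` column to split when mapping against several).
#' @param ref The reference the alignments were computed against.
#' @return A `cpb_pileup`: `counts` (5 x L matrix, rows A,C,G,T,-),
#'   `depth`, `span`, `insertions`, `width`, `ref`.
#' @export
build_pileup <- function(alignments, ref) {
  refseq <- as_sequence(ref)
  L <- nchar(refseq)
  if (nrow(alignments) > 0 &&
      (min(alignments$start) < 1 || max(alignments$end) > L))
    cpb_error("alignment coordinates outside the reference",
              "cpb_integrity_error")
  pp <- cpp_pileup(L, as.integer(alignments$start), alignments$cigar,
                   alignments$oriented)
  counts <- pp$counts
  rownames(counts) <- c("A", "C", "G", "T", "-")
  depth <- colSums(counts)
  structure(list(counts = counts, depth = depth, span = pp$span,
                 insertions = pp$insertions, width = mean(depth > 0),
                 ref = refseq),
            class = "cpb_pileup")
}

#' @export
print.cpb_pileup <- function(x, ...) {
  cat(sprintf("<pileup: %d positions, mean depth %.1f, width %.3f>\n",
              length(x$depth), mean(x$depth), x$width))
  invisible(x)
}

#' Extract a majority-vote consensus from a pileup
#'
#' At each reference position the plurality symbol among
#' \{A, C, G, T, deletion\} wins; a majority deletion removes the position.
#' An insertion is emitted at an anchor when more junction-spanning reads
#' support one identical inserted string than support no insertion (or any
#' other string). Zero-depth positions emit the reference base and are
#' flagged. Voting ties go to the reference allele (`tie_policy =
#' "reference"`) or to the first symbol in A,C,G,T,deletion order
#' (`"first"`).
#'
#' @param pileup A [build_pileup()] result.
#' @param ref The reference (defaults to the pileup's).
#' @param tie_policy `"reference"` or `"first"`.
#' @return A `cpb_consensus`: `sequence`, `calls` (per-position winning
#'   symbol), `zero_coverage` (positions), `insertions_called` (data.frame),
#'   `n_deletions` (majority-deletion positions), `ins_bases` (total
#'   inserted length), `width`.
#' @export
call_consensus <- function(pileup, ref = NULL, tie_policy = c("reference", "first")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(pileup, "cpb_pileup"))
  refseq <- if (is.null(ref)) pileup$ref else as_sequence(ref)
  L <- nchar(refseq)
  cm <- pileup$counts
  depth <- pileup$depth
  mx <- pmax(cm[1, ], cm[2, ], cm[3, ], cm[4, ], cm[5, ])
  win <- rep(0L, L)
  for (r in 5:1) win[cm[r, ] == mx] <- r
  if (tie_policy == "reference") {
    ref_idx <- match(strsplit(refseq, "", fixed = TRUE)[[1]],
                     c("A", "C", "G", "T"))
    ref_count <- cm[cbind(ref_idx, seq_len(L))]
    win[ref_count == mx] <- ref_idx[ref_count == mx]
  }
  zero <- which(depth == 0)
  if (length(zero)) {
    ref_idx2 <- match(substring(refseq, zero, zero), c("A", "C", "G", "T"))
    win[zero] <- ref_idx2
  }
  symbols <- c("A", "C", "G", "T", "")
  parts <- symbols[win]
  # insertion voting among junction-spanning reads
  ins_called <- data.frame(anchor = integer(0), seq = character(0),
                           count = integer(0), spanning = integer(0),
                           stringsAsFactors = FALSE)
  ins <- pileup$insertions
  if (nrow(ins) > 0) {
    for (anchor in unique(ins$anchor)) {
      rows <- ins[ins$anchor == anchor, , drop = FALSE]
      rows <- rows[order(-rows$count, rows$seq), , drop = FALSE]
      spanning <- pileup$span[anchor]
      no_ins <- spanning - sum(rows$count)
      top <- rows$count[1]
      runner <- max(c(no_ins, rows$count[-1], 0))
      if (top > runner) {
        parts[anchor] <- paste0(parts[anchor], rows$seq[1])
        ins_called <- rbind(ins_called, data.frame(
          anchor = anchor, seq = rows$seq[1], count = top,
          spanning = spanning, stringsAsFactors = FALSE))
      }
    }
  }
  sequence <- paste(parts, collapse = "")
  n_del <- sum(win == 5L)
  ins_bases <- if (nrow(ins_called)) sum(nchar(ins_called$seq)) else 0L
  structure(list(sequence = sequence, calls = symbols[win],
                 zero_coverage = zero, insertions_called = ins_called,
                 n_deletions = n_del, ins_bases = ins_bases,
                 width = pileup$width),
            class = "cpb_consensus")
}

#' @export
print.cpb_consensus <- function(x, ...) {
  cat(sprintf(
    "<consensus: %d bp (%d majority deletions, %d inserted bases), width %.3f>\n",
    nchar(x$sequence), x$n_deletions, x$ins_bases, x$width))
  invisible(x)
}
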