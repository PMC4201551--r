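# Independent oracles and small fixture builders shared across test files.

# Exhaustive-substring Mott oracle: best interval by (sum, leftmost start,
# longest), computed over all O(n^2) substrings from shared prefix sums.
mott_oracle <- function(p, limit) {
  n <- length(p)
  S <- cumsum(c(0, limit - p))
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- S[j + 1] - S[i]
      if (is.null(best) || s > best$s ||
          (s == best$s && (i < best$i || (i == best$i && j > best$j))))
        best <- list(s = s, i = i, j = j)
    }
  }
  if (best$s > 0) c(best$i, best$j) else c(0L, 0L)
}

# Full dynamic-programming mapping-cost oracle (global on the read, local on
# the reference) via Biostrings::pairwiseAlignment with the same cost model.
map_cost_oracle <- function(read, ref, mismatch = 2, gap = 3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0,
                                                  mismatch = -mismatch,
                                                  baseOnly = TRUE)
  pw <- Biostrings::pairwiseAlignment(read, ref, type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = -gap)
  -Biostrings::score(pw)
}

# Affine-gap global alignment cost oracle (unit mismatch, open 2, extend 1),
# matching the consensus-to-reference aligner's model (gap cost 2 + g).
global_affine_cost_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  pw <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = -2, gapExtension = -1)
  -Biostrings::score(pw)
}

random_seq <- function(n, gc = 0.39) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_bases <- function(seq, positions) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

one_read <- function(bases, quals = rep(35L, nchar(bases)), id = "r1", ...) {
  read_set(id, bases, list(quals), ...)
}

site_keys <- function(v) paste0(ifelse(v$type == "ins", "i", "p"), v$position)

strip_rows <- function(d) { rownames(d) <- NULL; d }
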