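# Quality trimming and read subsampling performed before mapping/assembly.

#' Trimming parameters
#'
#' Two trimming modes are supported. `error_prob_limit` is Mott-style
#' trimming on claimed error probabilities: the kept interval is the
#' contiguous subsequence maximizing `sum(limit - p_i)` (ties broken
#' leftmost, then longest). The operative parameter is the error-probability
#' `limit` itself (0.05 is the semiconductor-platform preset, 0.01 the
#' short-read preset). `sliding_window` truncates a read at the first
#' window of `window_length` bases whose mean claimed PHRED falls below
#' `window_phred`.
#'
#' @param mode `"error_prob_limit"` or `"sliding_window"`.
#' @param limit Error-probability limit for Mott trimming.
#' @param window_length,window_phred Sliding-window length and PHRED
#'   threshold.
#' @param min_length Reads shorter than this after trimming are dropped
#'   (30 for the Mott presets; 20 in the sliding-window preset).
#' @param drop_ambiguous Drop reads still containing `N` after trimming.
#' @return A `cpb_trim_params` list.
#' @export
trim_params <- function(mode = c("error_prob_limit", "sliding_window"),
                        limit = 0.05, window_length = 20, window_phred = 17,
                        min_length = if (match.arg(mode) == "sliding_window") 20 else 30,
                        drop_ambiguous = TRUE) {
  mode <- match.arg(mode)
  if (limit <= 0 || limit >= 1)
    cpb_error("limit must be in (0, 1)", "cpb_parameter_error")
  if (min_length < 1)
    cpb_error("min_length must be >= 1", "cpb_parameter_error")
  structure(list(mode = mode, limit = limit, window_length = window_length,
                 window_phred = window_phred, min_length = min_length,
                 drop_ambiguous = drop_ambiguous),
            class = "cpb_trim_params")
}

trim_interval <- function(bases, quals, params) {
  # returns c(start, end) of the kept interval, or c(0, 0) when dropped
  if (params$mode == "error_prob_limit") {
    p <- phred_to_error(quals)
    if (grepl("N", bases, fixed = TRUE)) {
      nn <- gregexpr("N", bases, fixed = TRUE)[[1]]
      p[nn] <- 1                      # N counts as a certain error
    }
    iv <- cpp_mott_trim(list(p), params$limit)[1, ]
  } else {
    n <- length(quals)
    w <- params$window_length
    keep_to <- n
    if (n >= w) {
      cs <- cumsum(c(0, quals))
      means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
      bad <- which(means < params$window_phred)
      if (length(bad)) keep_to <- bad[1] - 1L
    }
    iv <- if (keep_to >= 1) c(1L, keep_to) else c(0L, 0L)
  }
  iv
}

#' Trim a single read
#'
#' @param read A length-1 [read_set()].
#' @param params [trim_params()].
#' @return The trimmed read (a length-1 read set), or `NULL` when dropped.
#' @export
trim_read <- function(read, params = trim_params()) {
  stopifnot(inherits(read, "cpb_reads"), length(read) == 1)
  out <- trim_set(read, params)$reads
  if (length(out) == 0) NULL else out
}

#' Trim a read set
#'
#' Order-preserving. When one mate of a pair is dropped, the surviving mate
#' is retained as a single read. Reads containing `N` after trimming are
#' dropped when `drop_ambiguous`; kept intervals shorter than `min_length`
#' are dropped.
#'
#' @param reads A [read_set()].
#' @param params [trim_params()].
#' @return `list(reads = <trimmed read_set>, report = <list of counts>)`.
#' @export
trim_set <- function(reads, params = trim_params()) {
  stopifnot(inherits(reads, "cpb_reads"))
  n <- length(reads)
  if (n == 0)
    return(list(reads = reads,
                report = list(input = 0L, kept = 0L, dropped = 0L,
                              mean_length_in = 0, mean_length_out = 0)))
  if (params$mode == "error_prob_limit") {
    probs <- lapply(seq_len(n), function(i) {
      p <- phred_to_error(reads$quals[[i]])
      if (grepl("N", reads$bases[i], fixed = TRUE)) {
        nn <- gregexpr("N", reads$bases[i], fixed = TRUE)[[1]]
        p[nn] <- 1
      }
      p
    })
    iv <- cpp_mott_trim(probs, params$limit)
  } else {
    iv <- t(vapply(seq_len(n), function(i)
      trim_interval(reads$bases[i], reads$quals[[i]], params), integer(2)))
  }
  start <- iv[, 1]; end <- iv[, 2]
  keep <- start > 0 & (end - start + 1) >= params$min_length
  bases <- substr(reads$bases, start, end)
  if (params$drop_ambiguous)
    keep <- keep & !grepl("N", bases, fixed = TRUE)
  idx <- which(keep)
  out <- read_set(reads$id[idx], bases[idx],
                  lapply(idx, function(i) reads$quals[[i]][start[i]:end[i]]),
                  platform = reads$platform[idx], mate = reads$mate[idx],
                  pair_id = reads$pair_id[idx])
  # orphaned mates become singles
  if (any(!is.na(out$pair_id))) {
    paired <- !is.na(out$pair_id)
    orphan <- paired & !(out$pair_id %in% out$pair_id[paired][
      duplicated(out$pair_id[paired])])
    out$mate[orphan] <- NA_integer_
    out$pair_id[orphan] <- NA_character_
  }
  list(reads = out,
       report = list(input = n, kept = length(idx), dropped = n - length(idx),
                     mean_length_in = mean(nchar(reads$bases)),
                     mean_length_out = if (length(idx)) mean(nchar(bases[idx])) else 0))
}

#' Randomly subsample reads
#'
#' Uniform sampling without replacement; mate pairs are sampled atomically.
#' Deterministic under `seed`. Requesting more reads than available returns
#' all reads with a warning.
#'
#' @param reads A [read_set()].
#' @param n Target number of reads (pairs count as two).
#' @param seed Integer seed.
#' @return A [read_set()].
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  stopifnot(inherits(reads, "cpb_reads"), n >= 0)
  total <- length(reads)
  if (n >= total) {
    if (n > total)
      warning(sprintf("requested %d reads but only %d available; returning all",
                      n, total))
    return(reads)
  }
  if (n == 0) return(reads[integer(0)])
  set.seed(seed)
  unit <- ifelse(is.na(reads$pair_id), paste0("single:", seq_len(total)),
                 paste0("pair:", reads$pair_id))
  units <- unique(unit)
  perm <- sample(units)
  sizes <- as.integer(table(unit)[perm])
  cum <- cumsum(sizes)
  take <- perm[cum <= n]
  reads[which(unit %in% take)]
}
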