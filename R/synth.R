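# Synthetic study material: plastome-like truth genomes, implanted variant
# truth sets, and platform-specific shotgun read simulation. Downstream
# stages are tested end-to-end against these generators.

#' Specify a synthetic plastome
#'
#' Defaults emulate a chloroplast genome: ~130 kb, AT-rich (GC 39%), two
#' inverted repeats, and an enriched homopolymer spectrum admitting runs of
#' up to 17 identical bases.
#'
#' @param length Genome length in bases.
#' @param gc_fraction Target GC content.
#' @param ir_length Length of each inverted-repeat copy (0 disables IRs).
#' @param homopolymer_boost Named numeric vector mapping run length to the
#'   expected number of implanted runs per 100 kb.
#' @param seed Integer seed (mandatory; generation is deterministic).
#' @return A `cpb_genome_spec` list.
#' @export
genome_spec <- function(length = 130000, gc_fraction = 0.39,
                        ir_length = 20000,
                        homopolymer_boost = default_homopolymer_boost(),
                        seed = 1L) {
  if (length < 1000)
    cpb_error("genome length must be at least 1,000 bases", "cpb_parameter_error")
  if (2 * ir_length >= length)
    cpb_error("infeasible IR size: 2 * ir_length must be < length",
              "cpb_parameter_error")
  structure(list(length = as.integer(length), gc_fraction = gc_fraction,
                 ir_length = as.integer(ir_length),
                 homopolymer_boost = homopolymer_boost,
                 seed = as.integer(seed)),
            class = "cpb_genome_spec")
}

#' @rdname genome_spec
#' @export
default_homopolymer_boost <- function() {
  c(`5` = 150, `6` = 70, `7` = 30, `8` = 15, `9` = 8, `10` = 5, `11` = 3,
    `12` = 2.5, `13` = 2, `14` = 1.5, `15` = 1, `16` = 0.8, `17` = 0.7)
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

implant_homopolymers <- function(chars, boost, seed_offset = 0) {
  L <- length(chars)
  lens <- as.integer(names(boost))
  counts <- round(boost * L / 1e5)
  blocked <- logical(L)
  for (i in rev(seq_along(lens))) {     # longest first so they fit
    l <- lens[i]
    n <- counts[i]
    if (n < 1) next
    placed <- 0
    tries <- 0
    while (placed < n && tries < 50 * n) {
      tries <- tries + 1
      s <- sample.int(L - l - 2, 1) + 1
      if (any(blocked[(s - 1):(s + l)])) next
      base <- sample(c("A", "T", "C", "G"), 1, prob = c(.4, .4, .1, .1))
      chars[s:(s + l - 1)] <- base
      # break up accidental extensions so the implanted run stays maximal
      if (chars[s - 1] == base) chars[s - 1] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      if (chars[s + l] == base) chars[s + l] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      blocked[(s - 1):(s + l)] <- TRUE
      placed <- placed + 1
    }
  }
  chars
}

#' Generate a synthetic plastome
#'
#' Bases are drawn i.i.d. at the requested GC content, a homopolymer
#' spectrum is implanted (AT-biased, as in real plastomes), and, when
#' `ir_length > 0`, the genome is laid out as
#' `LSC | IR | SSC | reverse-complement(IR)` with the two IR copies
#' annotated in `ir_regions`.
#'
#' @param spec A [genome_spec()].
#' @return A [plastome()] with `ir_regions` set when IRs were requested.
#' @export
generate_plastome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "cpb_genome_spec"))
  set.seed(spec$seed)
  L <- spec$length
  ir <- spec$ir_length
  core_len <- L - ir                       # unique sequence + one IR copy
  chars <- sample_bases(core_len, spec$gc_fraction)
  chars <- implant_homopolymers(chars, spec$homopolymer_boost)
  if (ir == 0) {
    return(plastome(paste(chars, collapse = ""), id = "synthetic_plastome"))
  }
  rest <- L - 2 * ir
  lsc <- round(rest * 0.6)
  ssc <- rest - lsc
  core <- paste(chars, collapse = "")      # LSC | IR | SSC
  ir_seq <- substr(core, lsc + 1, lsc + ir)
  seq <- paste0(core, revcomp(ir_seq))
  plastome(seq, id = "synthetic_plastome",
           ir_regions = list(c(lsc + 1L, lsc + ir),
                             c(lsc + ir + ssc + 1L, L)))
}

#' Specify a truth variant set
#'
#' Defaults mirror the scale of a wild-vs-cultivated rice chloroplast
#' comparison: 128 variants comprising 92 SNPs, 5 MNVs, 13 insertions and
#' 18 deletions, with most indels placed inside homopolymer runs.
#'
#' @param n_snp,n_mnv,n_ins,n_del Event counts (realized exactly, or an
#'   error is raised).
#' @param indel_length_distribution Named probability vector over indel
#'   lengths.
#' @param mnv_lengths Candidate MNV lengths (sampled uniformly).
#' @param homopolymer_targeting_fraction Fraction of indels placed inside
#'   homopolymer runs (length 2-9).
#' @param avoid_ir Keep variants out of annotated inverted repeats. Real
#'   plastomes homogenize their IR copies, so a variant confined to one
#'   copy would be biologically atypical; restricting events to
#'   single-copy regions keeps the two IRs identical.
#' @param seed Integer seed.
#' @return A `cpb_variant_spec` list.
#' @export
variant_spec <- function(n_snp = 92, n_mnv = 5, n_ins = 13, n_del = 18,
                         indel_length_distribution = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                         mnv_lengths = 2:4,
                         homopolymer_targeting_fraction = 0.8,
                         avoid_ir = TRUE,
                         seed = 1L) {
  structure(list(n_snp = n_snp, n_mnv = n_mnv, n_ins = n_ins, n_del = n_del,
                 indel_length_distribution = indel_length_distribution,
                 mnv_lengths = mnv_lengths,
                 homopolymer_targeting_fraction = homopolymer_targeting_fraction,
                 avoid_ir = avoid_ir,
                 seed = as.integer(seed)),
            class = "cpb_variant_spec")
}

sample_indel_len <- function(n, dist) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

#' Implant a truth variant set into a genome
#'
#' Events are non-overlapping (minimum 12 bp apart) and left-normalized;
#' applying the returned truth list to the original genome with
#' [apply_variants()] reconstructs the mutated sequence exactly.
#'
#' @param genome A [plastome()] or DNA string.
#' @param spec A [variant_spec()].
#' @return `list(sequence = <mutated string>, truth = <variant data.frame>)`,
#'   the truth table sorted by position.
#' @export
implant_variants <- function(genome, spec = variant_spec()) {
  seq <- as_sequence(genome)
  set.seed(spec$seed)
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  runs <- homopolymer_runs(seq)
  hp_runs <- runs[runs$len >= 2 & runs$len <= 9 & runs$start > 13 &
                    runs$end < L - 13, , drop = FALSE]
  blocked <- logical(L)
  if (isTRUE(spec$avoid_ir) && inherits(genome, "cpb_plastome") &&
      !is.null(genome$ir_regions)) {
    for (iv_ir in genome$ir_regions)
      blocked[iv_ir[1]:iv_ir[2]] <- TRUE
    hp_runs <- hp_runs[!blocked[hp_runs$start], , drop = FALSE]
  }
  margin <- 12L
  claim <- function(s, e) {
    if (s < 2 || e > L - 2) return(FALSE)
    if (any(blocked[s:e])) return(FALSE)
    blocked[max(1, s - margin):min(L, e + margin)] <<- TRUE
    TRUE
  }
  rows <- list()
  add_row <- function(position, type, ref_allele, alt_allele) {
    rows[[length(rows) + 1]] <<- data.frame(
      position = as.integer(position), type = type,
      ref_allele = ref_allele, alt_allele = alt_allele,
      stringsAsFactors = FALSE)
  }
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  place <- function(n, fn) {
    placed <- 0; tries <- 0
    while (placed < n) {
      if ((tries <- tries + 1) > 300 * max(1, n))
        cpb_error("could not place all variants without overlap",
                  "cpb_parameter_error")
      if (fn()) placed <- placed + 1
    }
  }
  # deletions and insertions, homopolymer-targeted or not
  n_hp_del <- round(spec$n_del * spec$homopolymer_targeting_fraction)
  n_hp_ins <- round(spec$n_ins * spec$homopolymer_targeting_fraction)
  if (nrow(hp_runs) == 0) n_hp_del <- n_hp_ins <- 0
  place(n_hp_del, function() {
    r <- hp_runs[sample.int(nrow(hp_runs), 1), ]
    l <- min(sample_indel_len(1, spec$indel_length_distribution), r$len)
    if (!claim(r$start, r$start + l - 1)) return(FALSE)
    add_row(r$start, "del", paste(rep(r$base, l), collapse = ""), "-")
    TRUE
  })
  place(spec$n_del - n_hp_del, function() {
    l <- sample_indel_len(1, spec$indel_length_distribution)
    p <- sample.int(L - l - 13, 1) + 6
    if (!claim(p, p + l - 1)) return(FALSE)
    add_row(p, "del", substr(seq, p, p + l - 1), "-")
    TRUE
  })
  place(n_hp_ins, function() {
    r <- hp_runs[sample.int(nrow(hp_runs), 1), ]
    l <- sample_indel_len(1, spec$indel_length_distribution)
    if (!claim(r$start - 1, r$start)) return(FALSE)
    add_row(r$start - 1, "ins", "-", paste(rep(r$base, l), collapse = ""))
    TRUE
  })
  place(spec$n_ins - n_hp_ins, function() {
    l <- sample_indel_len(1, spec$indel_length_distribution)
    p <- sample.int(L - l - 13, 1) + 6
    if (!claim(p, p + 1)) return(FALSE)
    add_row(p, "ins", "-", paste(sample(c("A", "C", "G", "T"), l, TRUE),
                                 collapse = ""))
    TRUE
  })
  place(spec$n_snp, function() {
    p <- sample.int(L - 13, 1) + 6
    if (!claim(p, p)) return(FALSE)
    add_row(p, "SNP", chars[p], other(chars[p]))
    TRUE
  })
  place(spec$n_mnv, function() {
    l <- sample(spec$mnv_lengths, 1)
    p <- sample.int(L - l - 13, 1) + 6
    if (!claim(p, p + l - 1)) return(FALSE)
    alt <- vapply(chars[p:(p + l - 1)], other, character(1))
    add_row(p, "MNV", substr(seq, p, p + l - 1), paste(alt, collapse = ""))
    TRUE
  })
  truth <- if (length(rows) == 0) empty_variants()
           else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  truth <- normalize_variants(truth, seq)
  truth <- truth[order(truth$position, truth$type), , drop = FALSE]
  rownames(truth) <- NULL
  truth$position <- as.integer(truth$position)
  list(sequence = apply_variants(seq, truth), truth = truth)
}

# ---------------------------------------------------------------------------
# Error models and read simulation
# ---------------------------------------------------------------------------

hp_rate_matrix <- function(AT = 0, GC = 0) {
  m <- matrix(0, nrow = 2, ncol = 17, dimnames = list(c("AT", "GC"), 1:17))
  if (length(AT) == 1) AT <- rep(AT, 17)
  if (length(GC) == 1) GC <- rep(GC, 17)
  m["AT", ] <- AT; m["GC", ] <- GC
  m
}

#' Platform error models for read simulation
#'
#' An error model combines a per-base substitution rate, per-homopolymer-run
#' indel rates (functions of base class AT/GC and run length, expressed as
#' 2 x 17 rate matrices), run-level systematic error probabilities (a run
#' drawn as "systematic" is miscalled in most reads, which is what produces
#' consensus-level indel errors), read length, pairing, insert size, and a
#' claimed-quality distribution.
#'
#' `illumina_error_model()`: substitution-dominated (rate 0.001), indel-free,
#' 100 bp paired reads with 500-600 bp inserts, mean claimed PHRED ~30.
#' `iontorrent_error_model()`: ~1% total error dominated by homopolymer
#' indels - deletions concentrated in short (2-5 bp) mostly G/C runs,
#' insertions in long (5-17 bp) mostly A/T runs - ~200 bp single reads,
#' mean claimed PHRED ~25.5.
#'
#' @param platform `"illumina"` or `"iontorrent"`.
#' @param substitution_rate Per-base substitution error probability.
#' @param read_length Either a single length or `c(mean, sd)`.
#' @param paired Emit mate pairs?
#' @param insert_size `c(mean, sd)` of the fragment length (paired mode).
#' @param qual_mean,qual_sd Claimed per-base PHRED distribution.
#' @param hp_del_rate,hp_ins_rate 2 x 17 matrices (rows `AT`, `GC`; columns
#'   run length) of per-read per-run indel probabilities.
#' @param sys_del_prob,sys_ins_prob 2 x 17 matrices of probabilities that a
#'   genome run is systematically miscalled.
#' @param sys_rate Per-read error probability at a systematic run.
#' @return A `cpb_error_model` list.
#' @export
error_model <- function(platform = c("illumina", "iontorrent"),
                        substitution_rate = 0.001,
                        read_length = 100, paired = FALSE,
                        insert_size = c(550, 50),
                        qual_mean = 30, qual_sd = 3,
                        hp_del_rate = hp_rate_matrix(),
                        hp_ins_rate = hp_rate_matrix(),
                        sys_del_prob = hp_rate_matrix(),
                        sys_ins_prob = hp_rate_matrix(),
                        sys_rate = 0.85) {
  platform <- match.arg(platform)
  if (length(read_length) == 1) read_length <- c(read_length, 0)
  structure(list(platform = platform, substitution_rate = substitution_rate,
                 read_length = read_length, paired = paired,
                 insert_size = insert_size, qual_mean = qual_mean,
                 qual_sd = qual_sd, hp_del_rate = hp_del_rate,
                 hp_ins_rate = hp_ins_rate, sys_del_prob = sys_del_prob,
                 sys_ins_prob = sys_ins_prob, sys_rate = sys_rate),
            class = "cpb_error_model")
}

#' @rdname error_model
#' @param ... Overrides passed to [error_model()].
#' @export
illumina_error_model <- function(...) {
  args <- list(platform = "illumina", substitution_rate = 0.001,
               read_length = 100, paired = TRUE, insert_size = c(550, 50),
               qual_mean = 30.5, qual_sd = 3)
  args[names(list(...))] <- list(...)
  do.call(error_model, args)
}

#' @rdname error_model
#' @export
iontorrent_error_model <- function(...) {
  del <- hp_rate_matrix()
  del["GC", 2:5] <- c(0.030, 0.060, 0.050, 0.030)
  del["GC", 6:17] <- 0.006
  del["AT", 2:5] <- 0.010
  del["AT", 6:17] <- 0.005
  ins <- hp_rate_matrix()
  ins["AT", 5:17] <- pmin(0.020 + 0.006 * (5:17 - 5), 0.09)
  ins["AT", 1:4] <- 0.0003
  ins["GC", ] <- 0.0003
  sdel <- hp_rate_matrix()
  sdel["GC", 2:5] <- 0.005
  sdel["AT", 2:5] <- 0.0008
  sins <- hp_rate_matrix()
  sins["AT", 5:17] <- 0.008
  args <- list(platform = "iontorrent", substitution_rate = 0.002,
               read_length = c(200, 20), paired = FALSE,
               qual_mean = 25.5, qual_sd = 4,
               hp_del_rate = del, hp_ins_rate = ins,
               sys_del_prob = sdel, sys_ins_prob = sins, sys_rate = 0.85)
  args[names(list(...))] <- list(...)
  do.call(error_model, args)
}

#' Simulate shotgun reads from a genome
#'
#' Reads are sampled uniformly from both strands (paired mode emits proper
#' forward/reverse mates with sampled insert sizes). Substitution errors are
#' per-base Bernoulli draws; homopolymer indel errors are per-run Bernoulli
#' draws whose rates depend on base class and run length, with a subset of
#' genome runs drawn as systematically miscalled. Claimed base qualities are
#' drawn independently of the error truth. An error log (one row per
#' simulated error, with homopolymer context) is attached as
#' `attr(result, "error_log")`.
#'
#' @param genome A [plastome()] or DNA string.
#' @param model An [error_model()].
#' @param coverage Target fold-coverage (> 0).
#' @param seed Integer seed.
#' @return A [read_set()] with `attr "error_log"`.
#' @export
simulate_reads <- function(genome, model, coverage, seed = 1L) {
  stopifnot(inherits(model, "cpb_error_model"))
  if (coverage <= 0)
    cpb_error("coverage must be > 0", "cpb_parameter_error")
  set.seed(seed)
  seq <- as_sequence(genome)
  L <- nchar(seq)
  rl_mean <- model$read_length[1]
  rl_sd <- model$read_length[2]

  if (model$paired) {
    n_frag <- max(1, round(coverage * L / (2 * rl_mean)))
    rl <- rep(round(rl_mean), n_frag)
    flen <- round(rnorm(n_frag, model$insert_size[1], model$insert_size[2]))
    flen <- pmax(flen, 2 * rl + 2)
    flen <- pmin(flen, L)
    fstart <- 1 + floor(runif(n_frag) * (L - flen + 1))
    s <- c(fstart, fstart + flen - rl)
    e <- c(fstart + rl - 1, fstart + flen - 1)
    flip <- c(rep(FALSE, n_frag), rep(TRUE, n_frag))   # mate 2 reported as rc
    mate <- c(rep(1L, n_frag), rep(2L, n_frag))
    pair_id <- rep(sprintf("frag_%07d", seq_len(n_frag)), 2)
    ids <- paste0(pair_id, "/", mate)
  } else {
    n_reads <- max(1, round(coverage * L / rl_mean))
    rl <- round(rnorm(n_reads, rl_mean, rl_sd))
    rl <- pmin(pmax(rl, 40), min(400, L))
    s <- 1 + floor(runif(n_reads) * (L - rl + 1))
    e <- s + rl - 1
    flip <- runif(n_reads) < 0.5
    mate <- rep(NA_integer_, n_reads)
    pair_id <- rep(NA_character_, n_reads)
    ids <- sprintf("sim_%s_%07d", model$platform, seq_len(n_reads))
  }
  n <- length(s)
  bases <- substring(seq, s, e)

  log_read <- integer(0); log_kind <- character(0)
  log_class <- character(0); log_len <- integer(0)

  # homopolymer indel errors, one event max per run per read
  runs <- homopolymer_runs(seq)
  runs <- runs[runs$len >= 2, , drop = FALSE]
  if (nrow(runs) > 0 &&
      (any(model$hp_del_rate > 0) || any(model$hp_ins_rate > 0))) {
    lencap <- pmin(runs$len, 17L)
    cls <- ifelse(runs$base %in% c("A", "T"), "AT", "GC")
    sys_del <- runif(nrow(runs)) < model$sys_del_prob[cbind(cls, lencap)]
    sys_ins <- runif(nrow(runs)) < model$sys_ins_prob[cbind(cls, lencap)]
    lo <- findInterval(s, runs$start) + 1L       # first run with start > s
    hi <- findInterval(e - 1L, runs$start)       # runs with start <= e-1
    cnt <- pmax(0L, hi - lo + 1L)
    ri <- rep.int(seq_len(n), cnt)
    ki <- sequence(cnt, from = lo)
    inside <- runs$end[ki] <= e[ri] - 1L & runs$start[ki] >= s[ri] + 1L
    ri <- ri[inside]; ki <- ki[inside]
    p_del <- ifelse(sys_del[ki], model$sys_rate,
                    model$hp_del_rate[cbind(cls[ki], lencap[ki])])
    p_ins <- ifelse(sys_ins[ki], model$sys_rate,
                    model$hp_ins_rate[cbind(cls[ki], lencap[ki])])
    do_del <- runif(length(ri)) < p_del
    do_ins <- !do_del & runif(length(ri)) < p_ins
    ev_r <- c(ri[do_del], ri[do_ins])
    ev_k <- c(ki[do_del], ki[do_ins])
    ev_kind <- c(rep("del", sum(do_del)), rep("ins", sum(do_ins)))
    if (length(ev_r)) {
      ord <- order(ev_r, -runs$start[ev_k])      # per read, right to left
      ev_r <- ev_r[ord]; ev_k <- ev_k[ord]; ev_kind <- ev_kind[ord]
      ins_len <- ifelse(ev_kind == "ins",
                        ifelse(runif(length(ev_r)) < 0.9, 1L, 2L), 0L)
      for (grp in split(seq_along(ev_r), ev_r)) {
        rd <- ev_r[grp[1]]
        b <- bases[rd]
        for (t in grp) {
          local <- runs$start[ev_k[t]] - s[rd] + 1L
          if (ev_kind[t] == "del") {
            b <- paste0(substr(b, 1, local - 1), substr(b, local + 1, nchar(b)))
          } else {
            b <- paste0(substr(b, 1, local - 1),
                        strrep(runs$base[ev_k[t]], ins_len[t]),
                        substr(b, local, nchar(b)))
          }
        }
        bases[rd] <- b
      }
      log_read <- c(log_read, ev_r)
      log_kind <- c(log_kind, ev_kind)
      log_class <- c(log_class, cls[ev_k])
      log_len <- c(log_len, runs$len[ev_k])
    }
  }

  # substitution errors
  if (model$substitution_rate > 0) {
    cur_len <- nchar(bases)
    nsub <- rbinom(n, cur_len, model$substitution_rate)
    for (rd in which(nsub > 0)) {
      pos <- sample.int(cur_len[rd], nsub[rd])
      b <- strsplit(bases[rd], "", fixed = TRUE)[[1]]
      for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
      bases[rd] <- paste(b, collapse = "")
    }
    subs <- rep.int(seq_len(n), nsub)
    log_read <- c(log_read, subs)
    log_kind <- c(log_kind, rep("sub", length(subs)))
    log_class <- c(log_class, rep(NA_character_, length(subs)))
    log_len <- c(log_len, rep(NA_integer_, length(subs)))
  }

  bases[flip] <- revcomp(bases[flip])
  fin_len <- nchar(bases)
  quals <- lapply(fin_len, function(l)
    pmin(pmax(as.integer(round(rnorm(l, model$qual_mean, model$qual_sd))), 2L), 40L))
  out <- read_set(ids, bases, quals, platform = model$platform,
                  mate = mate, pair_id = pair_id)
  attr(out, "error_log") <- data.frame(
    read = log_read, kind = log_kind, class = log_class,
    run_length = log_len, stringsAsFactors = FALSE)
  out
}
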