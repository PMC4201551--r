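# Sequence and table I/O shared by all pipeline stages, plus the PHRED
# quality-score semantics used package-wide.

#' Convert PHRED scores to error probabilities (and back)
#'
#' The single quality-to-probability conversion used across the pipeline:
#' `p = 10^(-Q/10)`.
#'
#' @param q Integer PHRED scores in `[0, 62]`.
#' @param p Error probabilities in `(0, 1]`.
#' @return `phred_to_error()` returns probabilities; `error_to_phred()`
#'   returns (real-valued) PHRED scores.
#' @examples
#' phred_to_error(c(0, 20, 40))
#' error_to_phred(0.01)
#' @export
phred_to_error <- function(q) 10^(-q / 10)

#' @rdname phred_to_error
#' @export
error_to_phred <- function(p) -10 * log10(p)

cpb_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

# ---------------------------------------------------------------------------
# Plastome
# ---------------------------------------------------------------------------

#' Construct a plastome (chloroplast genome) object
#'
#' A plastome is a linear reference or truth genome: an uppercase `A/C/G/T`
#' string with an optional pair of inverted-repeat (IR) intervals. When IR
#' intervals are given, the second must be the reverse complement of the
#' first. Ambiguity codes are rejected.
#'
#' @param sequence DNA string (lowercase accepted, normalized to uppercase).
#' @param id Sequence identifier.
#' @param ir_regions Optional list of two integer pairs `c(start, end)`
#'   (1-based, inclusive) giving the two IR copies.
#' @param circular Reserved flag; the pipeline treats the genome as linear.
#' @return An object of class `cpb_plastome` with fields `id`, `sequence`,
#'   `ir_regions`, `circular`.
#' @examples
#' p <- plastome("acgtACGT", id = "toy")
#' nchar(p$sequence)
#' @export
plastome <- function(sequence, id = "plastome", ir_regions = NULL,
                     circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    cpb_error(sprintf(
      "plastome '%s': invalid character '%s' at position %d (only A/C/G/T allowed)",
      id, substr(sequence, bad, bad), bad), "cpb_format_error")
  }
  if (!is.null(ir_regions)) {
    if (length(ir_regions) != 2L)
      cpb_error("ir_regions must be a list of two (start, end) pairs",
                "cpb_parameter_error")
    a <- ir_regions[[1]]; b <- ir_regions[[2]]
    ira <- substr(sequence, a[1], a[2])
    irb <- substr(sequence, b[1], b[2])
    if (!identical(irb, revcomp(ira)))
      cpb_error("second IR interval is not the reverse complement of the first",
                "cpb_format_error")
  }
  structure(list(id = id, sequence = sequence, ir_regions = ir_regions,
                 circular = circular),
            class = "cpb_plastome")
}

#' @export
print.cpb_plastome <- function(x, ...) {
  cat(sprintf("<plastome '%s': %s bp, GC %.1f%%%s>\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              100 * gc_content(x$sequence),
              if (is.null(x$ir_regions)) "" else
                sprintf(", IR %d bp x2", x$ir_regions[[1]][2] - x$ir_regions[[1]][1] + 1)))
  invisible(x)
}

as_sequence <- function(x) {
  if (inherits(x, "cpb_plastome")) x$sequence else as.character(x)
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a FASTA file
#'
#' Single-record files are returned as a [plastome()]; multi-record files as
#' a named character vector in file order (e.g. assembly contigs). Lowercase
#' input is accepted and uppercased. Characters outside `A/C/G/T/N` raise a
#' format error naming the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param as One of `"auto"` (default: plastome for a single record,
#'   sequences otherwise), `"plastome"`, or `"sequences"`.
#' @return A `cpb_plastome` or a named character vector.
#' @export
read_fasta <- function(path, as = c("auto", "plastome", "sequences")) {
  as <- match.arg(as)
  if (!file.exists(path))
    cpb_error(sprintf("file not found: %s", path), "cpb_io_error")
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    cpb_error(sprintf("malformed FASTA '%s': %s", path,
                                      conditionMessage(e)), "cpb_format_error"))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0)
      cpb_error(sprintf(
        "FASTA '%s', record '%s': invalid character '%s' at position %d",
        path, names(seqs)[i], substr(seqs[[i]], bad, bad), bad),
        "cpb_format_error")
  }
  if (as == "plastome" || (as == "auto" && length(seqs) == 1L))
    return(plastome(seqs[[1]], id = names(seqs)[1]))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param x A [plastome()], a named character vector, or a contig table with
#'   columns `id` and `seq`.
#' @param path Output path. Lines are LF-terminated.
#' @param width Bases per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (inherits(x, "cpb_plastome")) x <- setNames(x$sequence, x$id)
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  set <- Biostrings::DNAStringSet(unname(unlist(x)))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reads and FASTQ
# ---------------------------------------------------------------------------

#' Construct a read set
#'
#' A read set stores shotgun reads with per-base PHRED qualities and platform
#' metadata. Base strings may contain `N`; qualities are integers in
#' `[0, 62]` and must match the base string lengths.
#'
#' @param id Character vector of read identifiers.
#' @param bases Character vector of base strings over `A,C,G,T,N`.
#' @param quals List of integer PHRED vectors, one per read.
#' @param platform `"illumina"`, `"iontorrent"`, or `NA`.
#' @param mate Integer vector (1 or 2) for paired reads, `NA` for single.
#' @param pair_id Character vector linking mates, `NA` for single reads.
#' @return An object of class `cpb_reads`.
#' @export
read_set <- function(id, bases, quals, platform = NA_character_,
                     mate = NA_integer_, pair_id = NA_character_) {
  n <- length(bases)
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  stopifnot(length(id) == n, length(quals) == n)
  bl <- nchar(bases)
  ql <- lengths(quals)
  if (any(bl != ql))
    cpb_error(sprintf("read '%s': %d bases but %d quality values",
                      id[which(bl != ql)[1]], bl[bl != ql][1], ql[bl != ql][1]),
              "cpb_format_error")
  qr <- if (n > 0) range(unlist(quals), na.rm = TRUE) else c(0, 0)
  if (n > 0 && (qr[1] < 0 || qr[2] > 62))
    cpb_error("PHRED qualities must lie in [0, 62]", "cpb_format_error")
  structure(list(id = id, bases = bases, quals = quals,
                 platform = rep_len(as.character(platform), n),
                 mate = rep_len(as.integer(mate), n),
                 pair_id = rep_len(as.character(pair_id), n)),
            class = "cpb_reads")
}

#' @export
length.cpb_reads <- function(x) length(x$bases)

#' @export
`[.cpb_reads` <- function(x, i) {
  read_set(x$id[i], x$bases[i], x$quals[i], x$platform[i], x$mate[i],
           x$pair_id[i])
}

#' @export
print.cpb_reads <- function(x, ...) {
  cat(sprintf("<read set: %d reads, mean length %.1f%s>\n", length(x),
              if (length(x)) mean(nchar(x$bases)) else 0,
              if (all(is.na(x$mate))) "" else
                sprintf(", %d paired", sum(!is.na(x$mate)))))
  invisible(x)
}

#' Read a FASTQ file (Sanger PHRED+33)
#'
#' @param path Path to a FASTQ file.
#' @param platform Optional platform tag attached to every read.
#' @param detect_pairs When `TRUE` (default), identifiers ending in `/1` or
#'   `/2` are interpreted as mates of the same fragment.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, platform = NA_character_, detect_pairs = TRUE) {
  if (!file.exists(path))
    cpb_error(sprintf("file not found: %s", path), "cpb_io_error")
  set <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")),
    error = function(e)
      cpb_error(sprintf("malformed FASTQ '%s': %s", path,
                        conditionMessage(e)), "cpb_format_error"))
  ids <- sub("\\s.*$", "", names(set))
  quals <- suppressWarnings(as.list(as(Biostrings::quality(set), "IntegerList")))
  set <- suppressWarnings(as(set, "DNAStringSet"))
  mate <- rep(NA_integer_, length(ids))
  pair_id <- rep(NA_character_, length(ids))
  if (detect_pairs && length(ids)) {
    m <- regmatches(ids, regexpr("/[12]$", ids))
    has <- grepl("/[12]$", ids)
    mate[has] <- as.integer(sub("/", "", m))
    pair_id[has] <- sub("/[12]$", "", ids[has])
  }
  read_set(ids, as.character(set), quals, platform = platform,
           mate = mate, pair_id = pair_id)
}

#' Write a read set to FASTQ (Sanger PHRED+33)
#'
#' @param reads A [read_set()].
#' @param path Output path. Lines are LF-terminated.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "cpb_reads"))
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(reads$bases)
  names(set) <- reads$id
  q <- Biostrings::PhredQuality(vapply(reads$quals, function(v)
    rawToChar(as.raw(v + 33L)), character(1)))
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(set, q))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variant tables
# ---------------------------------------------------------------------------

VARIANT_TYPES <- c("SNP", "MNV", "ins", "del")

normalize_allele <- function(x) {
  x <- as.character(x)
  x[x %in% c("-", "−", "", NA)] <- "-"
  toupper(x)
}

#' Read a variant table (TSV)
#'
#' Accepts the single-sample layout `(position, type, ref_allele,
#' alt_allele)` or the two-platform layout `(position, type, ref_allele,
#' allele_a, allele_b)`; extra columns are preserved. The absent-allele
#' symbol may be ASCII `-` or the typographic minus. Insertions are anchored
#' between `position` and `position + 1` and carry `ref_allele == "-"`;
#' deletions carry `alt_allele == "-"` with `position` the first deleted
#' base. A conflicting-site row may carry a slash-combined type such as
#' `SNP/del`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `data.frame` of validated rows.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path))
    cpb_error(sprintf("file not found: %s", path), "cpb_io_error")
  if (file.size(path) == 0) return(empty_variants())
  tbl <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(tbl) == 0) return(empty_variants())
  names(tbl) <- tolower(names(tbl))
  req <- c("position", "type", "ref_allele")
  if (!all(req %in% names(tbl)))
    cpb_error(sprintf("variant table '%s' must have columns %s", path,
                      paste(req, collapse = ", ")), "cpb_format_error")
  tbl$position <- as.integer(tbl$position)
  tbl$ref_allele <- normalize_allele(tbl$ref_allele)
  for (col in intersect(c("alt_allele", "allele_a", "allele_b"), names(tbl)))
    tbl[[col]] <- normalize_allele(tbl[[col]])
  toks <- unique(unlist(strsplit(as.character(tbl$type), "/", fixed = TRUE)))
  bad <- setdiff(toks, VARIANT_TYPES)
  if (length(bad))
    cpb_error(sprintf(
      "unknown variant type token(s) %s; accepted tokens: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(VARIANT_TYPES, collapse = ", ")), "cpb_format_error")
  single <- !grepl("/", tbl$type, fixed = TRUE)
  if ("alt_allele" %in% names(tbl)) {
    v <- tbl[single, , drop = FALSE]
    bad_ins <- v$type == "ins" & v$ref_allele != "-"
    bad_del <- v$type == "del" & v$alt_allele != "-"
    if (any(bad_ins | bad_del))
      cpb_error(sprintf(
        "variant table row at position %d violates the %s allele convention",
        v$position[which(bad_ins | bad_del)[1]],
        if (any(bad_ins)) "insertion" else "deletion"), "cpb_format_error")
  }
  tbl
}

empty_variants <- function() {
  data.frame(position = integer(0), type = character(0),
             ref_allele = character(0), alt_allele = character(0),
             stringsAsFactors = FALSE)
}

#' Write a variant table to TSV
#'
#' @param variants A variant `data.frame`.
#' @param path Output path; LF line endings, ASCII `-` for absent alleles.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format an insertion anchor
#'
#' Insertions sit between two reference bases; they are printed as
#' `"pos^pos+1"` (e.g. `"65465^65466"`).
#'
#' @param position Left base of the anchor (1-based).
#' @return Character vector of anchor labels.
#' @export
format_anchor <- function(position) {
  sprintf("%d^%d", as.integer(position), as.integer(position) + 1L)
}
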