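# Orchestration: per-platform trim -> map-consensus -> assemble -> variants,
# then cross-platform reconciliation, with deterministic per-stage seeds and
# plain-file artifacts.

#' Pipeline configuration
#'
#' Every stochastic stage derives its seed deterministically from the
#' global seed and the stage name, so a rerun with the same configuration
#' is bit-identical.
#'
#' @param reference A [plastome()].
#' @param platforms Named list; each element is
#'   `list(reads = <read_set>, trim = <trim_params>, subsample_n = NULL)`.
#' @param mapping [mapping_params()].
#' @param assembly [assembly_params()].
#' @param long_run Long-homopolymer threshold for reconciliation rule R4.
#' @param seed Global integer seed.
#' @param outdir Output directory for artifacts (`NULL`: return values
#'   only).
#' @return A `cpb_config` list.
#' @export
pipeline_config <- function(reference, platforms, mapping = mapping_params(),
                            assembly = assembly_params(k = 21),
                            long_run = 8, seed = 1L, outdir = NULL) {
  stopifnot(inherits(reference, "cpb_plastome"), length(platforms) >= 1)
  structure(list(reference = reference, platforms = platforms,
                 mapping = mapping, assembly = assembly, long_run = long_run,
                 seed = as.integer(seed), outdir = outdir),
            class = "cpb_config")
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(stage))) %% 2147483647)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the per-platform analysis
#'
#' Trims (and optionally subsamples) the platform's reads, maps them to the
#' reference and extracts the majority-vote mapping-consensus, calls and
#' annotates variants against the reference, and separately assembles the
#' reads de novo, polishes and scaffolds the contigs, and attempts to join
#' them into a de novo consensus.
#'
#' @param config A [pipeline_config()].
#' @param platform Name of the platform entry to run.
#' @return A list with `trim_report`, `mapping` (report + alignments),
#'   `consensus`, `variants` (annotated), `bias`, `contigs` (polished),
#'   `scaffold` (alignments), `denovo` (a `cpb_join`), and `manifest`.
#' @export
run_platform <- function(config, platform) {
  stopifnot(inherits(config, "cpb_config"))
  pf <- config$platforms[[platform]]
  if (is.null(pf)) cpb_error(sprintf("unknown platform '%s'", platform),
                             "cpb_parameter_error")
  ref <- config$reference
  tr <- trim_set(pf$reads, if (is.null(pf$trim)) trim_params() else pf$trim)
  reads <- tr$reads
  if (!is.null(pf$subsample_n))
    reads <- subsample_reads(reads, pf$subsample_n,
                             seed = stage_seed(config$seed,
                                               paste0(platform, "_subsample")))
  mp <- map_reads(reads, ref, config$mapping,
                  seed = stage_seed(config$seed, paste0(platform, "_map")))
  pp <- build_pileup(mp$alignments, ref)
  cons <- call_consensus(pp)
  alg <- align_consensus(cons$sequence, ref)
  vars <- extract_variants(alg)
  vars <- annotate_homopolymer(vars, ref)
  bias <- summarize_bias(vars)
  asm <- assemble(reads, config$assembly, reference = ref)
  pol <- polish_contigs(asm, reads, config$mapping,
                        seed = stage_seed(config$seed, paste0(platform, "_polish")))
  sal <- align_contigs(pol, ref)
  joined <- join_contigs(sal, pol, ref)
  manifest <- list(
    stage = "run_platform", platform = platform,
    package_version = as.character(utils::packageVersion("cpbarcode")),
    seed = config$seed,
    stage_seeds = list(map = stage_seed(config$seed, paste0(platform, "_map")),
                       polish = stage_seed(config$seed, paste0(platform, "_polish"))),
    n_reads_in = tr$report$input, n_reads_kept = tr$report$kept,
    mapped_fraction = mp$report$mapped_fraction,
    consensus_length = nchar(cons$sequence),
    n_variants = nrow(vars), n_contigs = nrow(pol),
    denovo = joined$type)
  out <- list(platform = platform, trim_report = tr$report, reads = reads,
              mapping = mp, pileup = pp, consensus = cons, variants = vars,
              bias = bias, contigs = pol, scaffold = sal, denovo = joined,
              manifest = manifest)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    pre <- file.path(config$outdir, platform)
    write_fasta(setNames(cons$sequence, paste0(platform, "_mapping_consensus")),
                paste0(pre, "_consensus.fasta"))
    write_tsv(data.frame(position = seq_along(pp$depth), depth = pp$depth),
              paste0(pre, "_depth.tsv"))
    write_variant_table(vars, paste0(pre, "_variants.tsv"))
    if (nrow(pol)) write_fasta(pol, paste0(pre, "_contigs.fasta"))
    write_tsv(sal[, setdiff(names(sal), "oriented")],
              paste0(pre, "_scaffolds.tsv"))
    if (joined$type == "consensus") {
      write_fasta(setNames(joined$sequence, paste0(platform, "_denovo_consensus")),
                  paste0(pre, "_denovo.fasta"))
    } else {
      write_tsv(joined$gaps, paste0(pre, "_gaps.tsv"))
    }
    jsonlite::write_json(manifest, paste0(pre, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Compare platforms and build the amended consensus
#'
#' Diffs the two platforms' mapping-consensus variant sets, gathers contig
#' and mapping-ambiguity evidence, resolves every discrepancy, applies the
#' shared variants plus the resolved alleles to the reference, and
#' validates the amended sequence by remapping the first platform's reads.
#'
#' @param config A [pipeline_config()] with exactly two platforms.
#' @param results Named list of two [run_platform()] results (computed when
#'   omitted).
#' @return A list with `records` (resolved discrepancies), `shared`,
#'   `amended` ([amend_consensus()] result), `residuals`
#'   ([validate_by_remap()] result), and the per-platform `results`.
#' @export
run_compare <- function(config, results = NULL) {
  stopifnot(inherits(config, "cpb_config"))
  pls <- names(config$platforms)
  if (length(pls) != 2)
    cpb_error("run_compare needs exactly two platforms", "cpb_parameter_error")
  if (is.null(results))
    results <- setNames(lapply(pls, function(p) run_platform(config, p)), pls)
  if (!all(pls %in% names(results)))
    cpb_error("missing platform artifact(s)", "cpb_parameter_error")
  ref <- config$reference
  core <- names(empty_variants())
  a <- results[[pls[1]]]; b <- results[[pls[2]]]
  records <- diff_variant_sets(a$variants[, core], b$variants[, core])
  shared <- attr(records, "shared")
  sources <- list()
  sources[[pls[1]]] <- contig_evidence(a$contigs, ref)
  sources[[pls[2]]] <- contig_evidence(b$contigs, ref)
  evidence <- gather_evidence(records, sources, ref,
                              alignments = list(a$mapping$alignments,
                                                b$mapping$alignments))
  resolved <- resolve_discrepancies(records, evidence, long_run = config$long_run)
  am <- amend_consensus(ref, resolved, shared)
  residuals <- validate_by_remap(am, a$reads, config$mapping,
                                 seed = stage_seed(config$seed, "remap"))
  out <- list(records = resolved, shared = shared, amended = am,
              residuals = residuals, results = results)
  if (!is.null(config$outdir)) {
    rep <- data.frame(
      no = seq_len(nrow(resolved)),
      type = ifelse(is.na(resolved$type_a), resolved$type_b,
                    ifelse(is.na(resolved$type_b), resolved$type_a,
                           ifelse(resolved$type_a == resolved$type_b,
                                  resolved$type_a,
                                  paste0(resolved$type_a, "/", resolved$type_b)))),
      position = ifelse(resolved$site == "anchor",
                        format_anchor(resolved$position), resolved$position),
      ref_allele = resolved$ref_allele,
      allele_a = resolved$allele_a, allele_b = resolved$allele_b,
      most_probable = resolved$resolved_allele,
      rule = resolved$rule, stringsAsFactors = FALSE)
    write_tsv(rep, file.path(config$outdir, "discrepancies.tsv"))
    write_fasta(setNames(am$sequence, "amended_consensus"),
                file.path(config$outdir, "amended.fasta"))
    write_variant_table(residuals, file.path(config$outdir, "residuals.tsv"))
  }
  out
}
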