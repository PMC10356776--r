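#' Analyze microdiversity evidence against a genome (in memory)
#'
#' Core driver behind [runMicrodiv()]: finds ORFs (unless a pre-built ORF
#' table is supplied), classifies every SNP allele against every
#' overlapping ORF, computes per-ORF statistics, applies the three decision
#' rules in order (candidate thresholds, mirror discard, suspect start) and
#' tallies the windowed category counts.
#'
#' @param genome A [GenomeRecord-class].
#' @param snps SNP data.frame ([callSnps()] / [readSnpVcf()] layout).
#' @param orfs Optional ORF data.frame; found with [findOrfs()] when NULL.
#' @param code A [geneticCode()] list.
#' @param matrix Scoring matrix (default [blosum62()]).
#' @param min_orf_nt Minimum ORF length (default 90).
#' @param mode ORF detection mode (see [findOrfs()]).
#' @param window_nt Bar-chart window width (default 15).
#' @param min_snps Minimum classified effects per informative ORF
#'   (default 4).
#' @param decision A [decisionConfig()].
#' @param coverage Optional per-position depth vector for the report.
#' @return A [MicrodivResult-class].
#' @export
analyzeMicrodiversity <- function(genome, snps, orfs = NULL,
                                  code = geneticCode(1),
                                  matrix = blosum62(),
                                  min_orf_nt = 90L,
                                  mode = "start2stop",
                                  window_nt = 15L, min_snps = 4L,
                                  decision = decisionConfig(),
                                  coverage = numeric(0)) {
  if (is.null(orfs))
    orfs <- findOrfs(genome, min_orf_nt = min_orf_nt, code = code,
                     mode = mode)
  effects <- classifyEffects(snps, orfs, genome, code = code,
                             matrix = matrix)
  stats <- computeOrfStats(orfs, effects, first_nt = decision$first_nt,
                           min_snps = min_snps)
  stats <- flagCandidates(stats, length(genome), decision)
  stats <- mirrorFilter(stats, length(genome), decision)
  stats <- flagSuspectStart(stats, decision)
  windows <- windowCategoryCounts(effects, length(genome),
                                  window_nt = window_nt)
  mirrors <- stats[!is.na(stats$shadowed_by),
                   c("orf_id", "shadowed_by"), drop = FALSE]
  names(mirrors) <- c("shadowed_orf", "shadowing_orf")
  rownames(mirrors) <- NULL
  new("MicrodivResult", genome = genome, orfs = orfs, snps = snps,
      effects = effects, stats = stats, windows = windows,
      mirrors = mirrors, coverage = as.numeric(coverage),
      params = list(min_orf_nt = min_orf_nt, mode = mode,
                    window_nt = window_nt, min_snps = min_snps,
                    decision = unclass(decision),
                    genetic_code = code$table_id))
}

#' Run the full pipeline on files
#'
#' End-to-end run: read the genome, find ORFs, obtain SNPs from exactly one
#' evidence source (a SAM of aligned reads/sequences, piled up and called
#' with the 2-read / 1%-of-depth thresholds, or a pre-called VCF), classify
#' substitutions, compute per-ORF statistics and decision flags, and write
#' the two result tables (`orfs.tsv`, `effects.tsv`), the mirror table
#' (`mirrors.tsv`), the SVG report (`report.svg`) and a run log
#' (`run.log`). Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param genome_path Reference FASTA (single record).
#' @param outdir Output directory (created if needed).
#' @param sam_path,vcf_path Exactly one must be non-NULL.
#' @param gff_paths Optional GFF3 files with external gene predictions,
#'   drawn as display tracks only.
#' @param circular Genome topology flag.
#' @param min_orf_nt,mode,table,window_nt,min_snps See
#'   [analyzeMicrodiversity()].
#' @param min_mapq Mapping-quality filter for SAM input (default 0).
#' @param min_alt_reads,min_alt_frac SNP-calling thresholds (defaults 2
#'   and 0.01).
#' @param decision A [decisionConfig()].
#' @param quiet Suppress progress messages.
#' @return A [MicrodivResult-class], invisibly.
#' @export
runMicrodiv <- function(genome_path, outdir, sam_path = NULL,
                        vcf_path = NULL, gff_paths = character(),
                        circular = FALSE, min_orf_nt = 90L,
                        mode = "start2stop", table = 1,
                        min_mapq = 0L, min_alt_reads = 2L,
                        min_alt_frac = 0.01, window_nt = 15L,
                        min_snps = 4L, decision = decisionConfig(),
                        quiet = FALSE) {
  if (is.null(sam_path) == is.null(vcf_path))
    stop("exactly one evidence source required: sam_path or vcf_path")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  code <- geneticCode(table)
  note("parameters: circular=%s min_orf_nt=%d mode=%s table=%d min_mapq=%d",
       circular, min_orf_nt, mode, code$table_id, min_mapq)
  note("parameters: min_alt_reads=%d min_alt_frac=%g window_nt=%d min_snps=%d",
       min_alt_reads, min_alt_frac, window_nt, min_snps)
  note(paste0("parameters: candidate_max=%g overprint_max=%g start_fold=%g ",
              "first_nt=%d containment_frac=%g min_first50_snps=%d"),
       decision$candidate_max_ratio, decision$overprint_max_ratio,
       decision$start_fold, decision$first_nt, decision$containment_frac,
       decision$min_first50_snps)
  genome <- stage("read_genome", readGenome(genome_path, circular = circular))
  note("genome: %s, %d nt, %s", genomeId(genome), length(genome),
       if (circular) "circular" else "linear")
  orfs <- stage("find_orfs",
                findOrfs(genome, min_orf_nt = min_orf_nt, code = code,
                         mode = mode))
  note("ORFs found: %d (+: %d, -: %d)", nrow(orfs),
       sum(orfs$strand == "+"), sum(orfs$strand == "-"))
  coverage <- numeric(0)
  if (!is.null(sam_path)) {
    segments <- stage("read_sam",
                      readAlignments(sam_path, genome, min_mapq = min_mapq,
                                     quiet = TRUE))
    note("alignments: %d kept, %d skipped by flag, %d below mapq",
         nrow(segments), attr(segments, "n_skipped_flag"),
         attr(segments, "n_skipped_mapq"))
    columns <- stage("pileup", pileupColumns(segments, genome))
    coverage <- coverageProfile(columns, length(genome))
    snps <- stage("call_snps",
                  callSnps(columns, genome, min_alt_reads = min_alt_reads,
                           min_alt_frac = min_alt_frac))
    note("SNPs called: %d positions, %d alleles", nrow(snps),
         sum(lengths(snps$alts)))
  } else {
    snps <- stage("read_vcf", readSnpVcf(vcf_path, quiet = TRUE))
    note("SNPs ingested from VCF: %d positions, %d alleles", nrow(snps),
         sum(lengths(snps$alts)))
  }
  features <- NULL
  if (length(gff_paths)) {
    features <- do.call(rbind, lapply(gff_paths, function(p)
      stage("read_gff", readGeneFeatures(p))))
    note("external features: %d from %d file(s)", nrow(features),
         length(gff_paths))
  }
  result <- stage("classify", analyzeMicrodiversity(
    genome, snps, orfs = orfs, code = code, window_nt = window_nt,
    min_snps = min_snps, decision = decision, coverage = coverage))
  eff <- effectTable(result)
  note("effects: %d (SYN %d, POS %d, NEG %d, STOP %d, UNKNOWN %d)",
       nrow(eff), sum(eff$category == "SYN"), sum(eff$category == "POS"),
       sum(eff$category == "NEG"), sum(eff$category == "STOP"),
       sum(eff$category == "UNKNOWN"))
  st <- orfStats(result)
  note("flags: candidate %d, overprint_candidate %d, mirror_discarded %d, suspect_start %d, insufficient_data %d",
       sum(.hasFlag(st$flags, "candidate")),
       sum(.hasFlag(st$flags, "overprint_candidate")),
       sum(.hasFlag(st$flags, "mirror_discarded")),
       sum(.hasFlag(st$flags, "suspect_start")),
       sum(.hasFlag(st$flags, "insufficient_data")))
  stage("write_tables", {
    writeOrfTable(st, file.path(outdir, "orfs.tsv"))
    writeEffectTable(eff, file.path(outdir, "effects.tsv"))
    writeMirrorTable(mirrorTable(result), file.path(outdir, "mirrors.tsv"))
  })
  stage("render_svg",
        renderReport(result, file.path(outdir, "report.svg"),
                     external_features = features))
  note("outputs written: orfs.tsv effects.tsv mirrors.tsv report.svg")
  con <- file(file.path(outdir, "run.log"), open = "wb")
  writeLines(log, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(result)
}
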