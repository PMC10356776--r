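#' Read a single-record reference genome from FASTA
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @param circular Logical; mark the genome as circular.
#' @return A [GenomeRecord-class]; the sequence is uppercased, and any
#'   character outside A, C, G, T, N is an error.
#' @export
readGenome <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as plain strings first: the DNA reader silently drops characters
  # outside its alphabet, and we want them to be a hard error instead
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("cannot read FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L)
    stop("multiple records in ", path,
         " (one reference genome per run; split multi-contig input)")
  id <- sub("\\s.*$", "", names(set)[1])
  seq <- toupper(as.character(set[[1]]))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("illegal character ", paste(bad, collapse = ","), " in ", path,
         " (genome alphabet is A,C,G,T,N)")
  GenomeRecord(id, seq, circular = circular)
}

#' Read aligned segments from a SAM file
#'
#' Ingests the output of a read mapper (e.g. bwa mem) for the pileup-based
#' SNP caller. Unmapped, secondary and supplementary records are skipped, as
#' are records below `min_mapq`; skip counts are reported as attributes and
#' via `message()`. The SAM `@SQ` header must match the genome id and
#' length.
#'
#' @param path Path to a SAM file (with header).
#' @param genome A [GenomeRecord-class] the alignments refer to.
#' @param min_mapq Minimum mapping quality to keep a record (default 0, i.e.
#'   no filter).
#' @param quiet Suppress the skip-count message.
#' @return data.frame with columns `query_id`, `pos` (1-based leftmost
#'   reference position), `mapq`, `cigar`, `seq`; attributes `n_skipped_flag`
#'   and `n_skipped_mapq` carry the skip counts.
#' @export
readAlignments <- function(path, genome, min_mapq = 0L, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(genomeId(genome) %in% names(hdr)))
    stop("SAM @SQ header lacks genome '", genomeId(genome), "'")
  if (hdr[[genomeId(genome)]] != length(genome))
    stop("SAM @SQ LN (", hdr[[genomeId(genome)]],
         ") differs from genome length (", length(genome), ")")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- rec$flag
  drop_flag <- bitwAnd(flag, 0x4) > 0 | bitwAnd(flag, 0x100) > 0 |
    bitwAnd(flag, 0x800) > 0
  drop_mapq <- !drop_flag & rec$mapq < min_mapq
  keep <- !drop_flag & !drop_mapq
  if (!quiet)
    message("readAlignments: kept ", sum(keep), " of ", length(flag),
            " records (", sum(drop_flag), " unmapped/secondary/supplementary, ",
            sum(drop_mapq), " below mapq ", min_mapq, ")")
  out <- data.frame(query_id = rec$qname[keep],
                    pos = rec$pos[keep],
                    mapq = rec$mapq[keep],
                    cigar = rec$cigar[keep],
                    seq = as.character(rec$seq)[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped_flag") <- sum(drop_flag)
  attr(out, "n_skipped_mapq") <- sum(drop_mapq)
  out
}

#' Read SNVs from a VCF 4.x file
#'
#' Only single-nucleotide variants are retained (reference and every
#' alternate allele of length 1); indels and MNVs are skipped with a
#' reported count. Multi-allelic records are kept as one SNP with several
#' alternate alleles. Depth (`INFO/DP`) and allele depths (`FORMAT/AD`,
#' first sample) are extracted when present; the AD reference count is
#' dropped so that `alt_counts` aligns with `alts`.
#'
#' @param path Path to a VCF file.
#' @param quiet Suppress the skip-count message.
#' @return SNP data.frame with columns `pos` (1-based), `ref`, `depth` and
#'   list columns `alts`, `alt_counts` (`NULL` entries when AD is absent).
#' @export
readSnpVcf <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(VariantAnnotation::readVcf(path, genome = "unknown"),
                error = function(e) stop("malformed VCF ", path, ": ",
                                         conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  altL <- lapply(rr$ALT, as.character)
  is_snv <- nchar(ref) == 1L &
    vapply(altL, function(a) length(a) > 0L && all(nchar(a) == 1L) &&
             all(a %in% c("A", "C", "G", "T")), logical(1)) &
    ref %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snv)
  if (!quiet && n_skip)
    message("readSnpVcf: skipped ", n_skip, " non-SNV record(s)")
  dp <- tryCatch(VariantAnnotation::info(v)$DP,
                 error = function(e) NULL)
  if (is.null(dp)) dp <- rep(NA_integer_, length(rr))
  ad <- tryCatch(VariantAnnotation::geno(v)$AD, error = function(e) NULL)
  idx <- which(is_snv)
  out <- data.frame(pos = BiocGenerics::start(rr)[idx],
                    ref = ref[idx],
                    depth = as.integer(dp[idx]),
                    stringsAsFactors = FALSE)
  out$alts <- I(altL[idx])
  out$alt_counts <- I(lapply(idx, function(i) {
    if (is.null(ad)) return(NULL)
    x <- ad[i, 1][[1]]
    if (is.null(x) || all(is.na(x))) return(NULL)
    as.integer(x[-1])  # drop the reference count
  }))
  bad <- vapply(seq_len(nrow(out)), function(i) {
    ac <- out$alt_counts[[i]]
    !is.null(ac) && length(ac) != length(out$alts[[i]])
  }, logical(1))
  if (any(bad))
    stop("VCF record at position ", out$pos[which(bad)[1]],
         ": AD field inconsistent with ALT alleles")
  rownames(out) <- NULL
  out
}

#' Read gene features from GFF3 for display tracks
#'
#' Extracts CDS/gene features from an external gene prediction (e.g.
#' Prodigal or PHANOTATE output) for the report's annotation lanes. These
#' features are never scored; scoring always uses the internal ORF set.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (default CDS and gene).
#' @return data.frame with columns `label`, `start`, `end` (1-based
#'   inclusive), `strand`, `source`.
#' @export
readGeneFeatures <- function(path, types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("cannot parse GFF3 ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% types]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("GFF3 feature without strand in ", path, " (strand required)")
  ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  ids[is.na(ids)] <- as.character(which(is.na(ids)))
  data.frame(label = ids,
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = strand,
             source = as.character(gr$source),
             stringsAsFactors = FALSE)
}

#' Write / read the per-ORF statistics table
#'
#' Tab-separated, one row per ORF, with the category counts, the pN/pS,
#' pNeg/pS and first-50-nt pNeg/pS ratios and the decision flags. Ratios are
#' rendered with two decimals; undefined ratios (0/0) as `NA` and infinite
#' ones (n/0) as `Inf`. Coordinates are 1-based inclusive.
#'
#' @param stats Per-ORF statistics data.frame (see [computeOrfStats()]).
#' @param path Output path.
#' @return `writeOrfTable` the path, invisibly; `readOrfTable` the parsed
#'   data.frame with numeric ratio columns (NA/Inf restored).
#' @export
writeOrfTable <- function(stats, path) {
  cols <- c("orf_id", "start", "end", "strand", "frame", "length_nt",
            "n_syn", "n_pos", "n_neg", "n_stop", "pn_ps", "pneg_ps",
            "n_snps_first50", "first50_pneg_ps", "flags")
  df <- stats
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  out <- df[cols]
  out$pn_ps <- .fmtRatio(df$pn_ps)
  out$pneg_ps <- .fmtRatio(df$pneg_ps)
  out$first50_pneg_ps <- .fmtRatio(df$first50_pneg_ps)
  out$flags[is.na(out$flags)] <- ""
  .writeTsv(out, path)
}

#' @rdname writeOrfTable
#' @export
readOrfTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (cc in c("start", "end", "frame", "length_nt", "n_syn", "n_pos",
               "n_neg", "n_stop", "n_snps_first50"))
    df[[cc]] <- as.integer(df[[cc]])
  for (cc in c("pn_ps", "pneg_ps", "first50_pneg_ps"))
    df[[cc]] <- suppressWarnings(
      ifelse(df[[cc]] == "NA", NA_real_,
             ifelse(df[[cc]] == "Inf", Inf, as.numeric(df[[cc]]))))
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Write the per-effect table
#'
#' One row per (SNP allele x overlapping ORF) substitution effect, with the
#' codon-level consequence and BLOSUM62 score. `genome_pos` is 1-based.
#'
#' @param effects Effect data.frame from [classifyEffects()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeEffectTable <- function(effects, path) {
  cols <- c("orf_id", "genome_pos", "ref_allele", "alt_allele",
            "codon_index", "codon_pos", "ref_codon", "alt_codon",
            "ref_aa", "alt_aa", "blosum_score", "category")
  df <- effects
  if (!nrow(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  out <- df[cols]
  out$blosum_score <- ifelse(is.na(df$blosum_score), "NA",
                             as.character(df$blosum_score))
  .writeTsv(out, path)
}

#' Write the mirror-relationship table
#'
#' Records which discarded candidate ORFs (shadowed) were explained by which
#' larger opposite-strand candidate (shadowing).
#'
#' @param mirrors data.frame with columns `shadowed_orf`, `shadowing_orf`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMirrorTable <- function(mirrors, path) {
  if (is.null(mirrors) || !nrow(mirrors))
    mirrors <- data.frame(shadowed_orf = character(),
                          shadowing_orf = character())
  .writeTsv(mirrors[c("shadowed_orf", "shadowing_orf")], path)
}

# deterministic TSV writer: UTF-8, LF, header, no quotes
.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
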