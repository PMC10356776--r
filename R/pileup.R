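#' Per-position base counts from aligned segments
#'
#' Minimal pileup over the reference: CIGAR operations M, `=` and X advance
#' reference and query and contribute the query base; I and S advance the
#' query only (inserted and soft-clipped bases contribute nothing); D and N
#' advance the reference only (the segment is absent from the deleted
#' positions). Depth counts A/C/G/T bases only; N bases are excluded from
#' both the counts and the depth. On circular genomes alignments may run
#' past the origin and are wrapped; on linear genomes running past the end
#' is an error naming the segment.
#'
#' @param segments Alignment data.frame from [readAlignments()].
#' @param genome A [GenomeRecord-class].
#' @return data.frame with one row per covered position: `pos` (1-based),
#'   `depth`, and counts `A`, `C`, `G`, `T`.
#' @export
pileupColumns <- function(segments, genome) {
  L <- length(genome)
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (nrow(segments)) {
    ops <- c("M", "=", "X")
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      segments$cigar, pos = segments$pos, ops = ops)
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
      segments$cigar, ops = ops)
    for (i in seq_len(nrow(segments))) {
      ri <- rr[[i]]; qi <- qr[[i]]
      if (!length(ri)) next
      refpos <- unlist(lapply(seq_along(ri), function(k)
        seq.int(BiocGenerics::start(ri)[k], BiocGenerics::end(ri)[k])),
        use.names = FALSE)
      qpos <- unlist(lapply(seq_along(qi), function(k)
        seq.int(BiocGenerics::start(qi)[k], BiocGenerics::end(qi)[k])),
        use.names = FALSE)
      if (any(refpos > L)) {
        if (!isCircular(genome))
          stop("segment '", segments$query_id[i],
               "' aligns past the end of linear genome (position ",
               max(refpos), " > ", L, ")")
        refpos <- ((refpos - 1L) %% L) + 1L
      }
      bases <- strsplit(segments$seq[i], "", fixed = TRUE)[[1]][qpos]
      bi <- match(bases, c("A", "C", "G", "T"))
      ok <- !is.na(bi)
      if (any(ok)) {
        idx <- (refpos[ok] - 1L) * 4L + bi[ok]
        add <- tabulate(idx, nbins = 4L * L)
        counts <- counts + matrix(add, nrow = 4L)
      }
    }
  }
  depth <- colSums(counts)
  covered <- which(depth > 0L)
  data.frame(pos = covered, depth = as.integer(depth[covered]),
             A = counts["A", covered], C = counts["C", covered],
             G = counts["G", covered], T = counts["T", covered],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call SNPs from pileup columns
#'
#' Applies the evidence thresholds: a non-reference base becomes an
#' alternate allele when it is supported by at least `min_alt_reads` reads
#' AND makes up at least `min_alt_frac` of the position's (A/C/G/T) depth.
#' The defaults, 2 reads and 1% of depth, are conjunctive. All qualifying
#' alternate bases of a position are reported as one multi-allelic SNP.
#'
#' @param columns Pileup data.frame from [pileupColumns()].
#' @param genome A [GenomeRecord-class] supplying the reference base.
#' @param min_alt_reads Minimum supporting reads per alternate allele
#'   (default 2).
#' @param min_alt_frac Minimum fraction of the position depth (default 0.01).
#' @return SNP data.frame (`pos`, `ref`, `depth`, list columns `alts`,
#'   `alt_counts`), one row per position with at least one qualifying
#'   alternate allele.
#' @export
callSnps <- function(columns, genome, min_alt_reads = 2L,
                     min_alt_frac = 0.01) {
  if (min_alt_reads < 1L) stop("min_alt_reads must be >= 1")
  if (!(min_alt_frac > 0 && min_alt_frac <= 1))
    stop("min_alt_frac must be in (0, 1]")
  if (!nrow(columns)) return(.emptySnpFrame())
  gchars <- strsplit(genomeSeq(genome), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", nrow(columns))
  for (i in seq_len(nrow(columns))) {
    pos <- columns$pos[i]
    refb <- gchars[pos]
    depth <- columns$depth[i]
    if (depth == 0L || !(refb %in% bases)) next  # no calls at reference N
    cnt <- c(A = columns$A[i], C = columns$C[i], G = columns$G[i],
             T = columns$T[i])
    altb <- bases[bases != refb & cnt >= min_alt_reads &
                    cnt / depth >= min_alt_frac]
    if (!length(altb)) next
    rows[[i]] <- list(pos = pos, ref = refb, depth = depth,
                      alts = altb, alt_counts = as.integer(cnt[altb]))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptySnpFrame())
  out <- data.frame(pos = vapply(rows, `[[`, integer(1), "pos"),
                    ref = vapply(rows, `[[`, character(1), "ref"),
                    depth = vapply(rows, `[[`, integer(1), "depth"),
                    stringsAsFactors = FALSE)
  out$alts <- I(lapply(rows, `[[`, "alts"))
  out$alt_counts <- I(lapply(rows, `[[`, "alt_counts"))
  out
}

#' Per-position coverage profile
#'
#' @param columns Pileup data.frame from [pileupColumns()].
#' @param genome_length Genome length.
#' @return Numeric vector of length `genome_length`; uncovered positions 0.
#' @export
coverageProfile <- function(columns, genome_length) {
  v <- numeric(genome_length)
  if (nrow(columns)) v[columns$pos] <- columns$depth
  v
}
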