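#' Six-frame ORF detection on linear and circular genomes
#'
#' Scans all six reading frames of the genome for open reading frames. In
#' `start2stop` mode an ORF runs from the leftmost in-frame start codon of an
#' open stretch to its terminating stop codon (stop included in the
#' coordinates); in `stop2stop` mode an ORF is the entire open stretch
#' between two consecutive in-frame stops. On circular genomes frames
#' continue across the origin and ORFs may wrap it; each ORF is reported
#' once and no ORF longer than the genome is emitted. Partial ORFs at the
#' edges of linear genomes (missing their stop, or for `stop2stop` their
#' 5' bounding stop) are not reported, because the per-ORF statistics need
#' well-defined boundaries.
#'
#' Coordinates are 1-based inclusive on the forward strand. For an ORF with
#' `wraps = TRUE` the interval covers `start..L` then `1..end`. `frame` is
#' `(start - 1) mod 3` for plus-strand ORFs and `(L - end) mod 3` for
#' minus-strand ORFs (0, 1 or 2 relative to the ORF's own strand).
#'
#' @param genome A [GenomeRecord-class].
#' @param min_orf_nt Minimum ORF length in nucleotides, stop codon included
#'   (default 90).
#' @param code A [geneticCode()] list; its `start_codons` drive
#'   `start2stop` mode.
#' @param mode `"start2stop"` (default) or `"stop2stop"`.
#' @return data.frame with columns `orf_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `frame`, `wraps`, `length_nt`, `source`, ordered by
#'   start, then strand, then frame.
#' @examples
#' g <- GenomeRecord("g", "ATGAAATAG")
#' findOrfs(g, min_orf_nt = 9)
#' @export
findOrfs <- function(genome, min_orf_nt = 90L, code = geneticCode(1),
                     mode = c("start2stop", "stop2stop")) {
  mode <- match.arg(mode)
  if (min_orf_nt < 3L) stop("min_orf_nt must be >= 3")
  L <- length(genome)
  circular <- isCircular(genome)
  fwd <- genomeSeq(genome)
  stops <- names(code$codons)[code$codons == "*"]
  res <- list(
    `+` = .scanOriented(fwd, L, circular, mode, code$start_codons, stops,
                        min_orf_nt),
    `-` = .scanOriented(.revcomp(fwd), L, circular, mode, code$start_codons,
                        stops, min_orf_nt))
  orfs <- do.call(rbind, lapply(names(res), function(strand) {
    o <- res[[strand]]
    if (!nrow(o)) return(NULL)
    if (strand == "+") {
      start <- o$ostart; end <- o$oend
    } else {
      # oriented coordinates count along the reverse complement; reflect
      start <- L - o$oend + 1L; end <- L - o$ostart + 1L
    }
    data.frame(start = start, end = end, strand = strand,
               length_nt = o$len, stringsAsFactors = FALSE)
  }))
  if (is.null(orfs) || !nrow(orfs)) {
    return(data.frame(orf_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), wraps = logical(),
                      length_nt = integer(), source = character(),
                      stringsAsFactors = FALSE))
  }
  orfs$wraps <- orfs$start > orfs$end
  orfs$frame <- ifelse(orfs$strand == "+", (orfs$start - 1L) %% 3L,
                       (L - orfs$end) %% 3L)
  orfs <- orfs[!duplicated(orfs[c("start", "end", "strand")]), , drop = FALSE]
  ord <- order(orfs$start, orfs$strand, orfs$frame)
  orfs <- orfs[ord, , drop = FALSE]
  orfs$orf_id <- sprintf("ORF_%03d", seq_len(nrow(orfs)))
  orfs$source <- "internal"
  rownames(orfs) <- NULL
  orfs[c("orf_id", "start", "end", "strand", "frame", "wraps", "length_nt",
         "source")]
}

# Scan one oriented sequence (1..L) for ORFs; returns oriented coordinates.
# For circular genomes the sequence is repeated so that frames continue
# across the origin even when L is not a multiple of 3 (the codon walk then
# threads through all frame residues); duplicates collapse modulo L.
.scanOriented <- function(s, L, circular, mode, start_codons, stop_codons,
                          min_len) {
  S <- if (circular) strrep(s, 7L) else s
  nS <- nchar(S)
  out <- list()
  for (f in 0:2) {
    ps <- seq.int(1L + f, nS - 2L, by = 3L)
    if (!length(ps)) next
    cods <- substring(S, ps, ps + 2L)
    isStop <- cods %in% stop_codons
    isStart <- cods %in% start_codons
    stopIdx <- which(isStop)
    if (!length(stopIdx)) next
    # open stretches: (lo, hi] in codon indices, ORF terminates at codon hi
    lo <- c(if (!circular) 0L, stopIdx[-length(stopIdx)])
    hi <- c(if (!circular) stopIdx[1L], stopIdx[-1L])
    for (j in seq_along(hi)) {
      a <- lo[j]; b <- hi[j]
      first <- if (mode == "start2stop") {
        if (b - 1L < a + 1L) next
        k <- which(isStart[(a + 1L):(b - 1L)])
        if (!length(k)) next
        # leftmost start codon whose ORF still fits the genome: on circular
        # genomes with L not a multiple of 3 an open stretch can exceed L
        k <- k[ps[b] + 2L - ps[a + k] + 1L <= L]
        if (!length(k)) next
        a + k[1L]
      } else {
        if (!circular && a == 0L) next  # 5' boundary stop missing
        a + 1L
      }
      if (first > b) next
      startNt <- ps[first]; endNt <- ps[b] + 2L
      len <- endNt - startNt + 1L
      if (len < min_len || len > L) next
      cs <- ((startNt - 1L) %% L) + 1L
      ce <- ((endNt - 1L) %% L) + 1L
      out[[length(out) + 1L]] <- c(cs, ce, len)
    }
  }
  if (!length(out))
    return(data.frame(ostart = integer(), oend = integer(), len = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(ostart = m[, 1L], oend = m[, 2L], len = m[, 3L])
  unique(df)
}

#' Offset of a genomic position within an ORF
#'
#' Returns the 0-based distance from the ORF's 5' end, walking in ORF
#' orientation (so for minus-strand ORFs the walk runs from `end` leftwards
#' along the forward strand), modular on origin-wrapping ORFs. Positions not
#' covered by the ORF give `NA`.
#'
#' @param pos 1-based forward-strand position(s).
#' @param orf One ORF row as returned by [findOrfs()] (or a list with
#'   `start`, `end`, `strand`, `wraps`).
#' @param genome_length Genome length in nucleotides.
#' @return Integer offset(s) in `[0, length_nt)`, or `NA` when outside.
#' @export
orfOffset <- function(pos, orf, genome_length) {
  L <- genome_length
  inside <- if (orf$wraps) pos >= orf$start | pos <= orf$end
            else pos >= orf$start & pos <= orf$end
  off <- if (orf$strand == "+") (pos - orf$start) %% L
         else (orf$end - pos) %% L
  ifelse(inside, as.integer(off), NA_integer_)
}

# ORF nucleotide sequence in reading orientation (start codon first).
.orfSequence <- function(orf, genomeChars) {
  L <- length(genomeChars)
  posSeq <- .coveredPositions(orf$start, orf$end, orf$wraps, L)
  s <- paste(genomeChars[posSeq], collapse = "")
  if (orf$strand == "-") .revcomp(s) else s
}

#' Reverse complement of a genome
#'
#' @param genome A [GenomeRecord-class].
#' @return A new `GenomeRecord` with the reverse-complemented sequence.
#' @export
reverseComplementGenome <- function(genome) {
  GenomeRecord(genomeId(genome), .revcomp(genomeSeq(genome)),
               circular = isCircular(genome))
}
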