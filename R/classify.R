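#' Classify SNP alleles against overlapping ORFs
#'
#' The core statistic of the method. Every alternate allele of every SNP is
#' evaluated against every ORF covering its position, on that ORF's own
#' strand and frame: the allele is placed in its codon (for minus-strand
#' ORFs both alleles are complemented first), the codon is substituted, and
#' the induced amino-acid change is categorized as
#' \describe{
#'   \item{SYN}{synonymous (equal non-stop amino acids);}
#'   \item{STOP}{stop gained or lost (exactly one side is `*`);}
#'   \item{NEG}{nonsynonymous with a negative BLOSUM62 score -- the
#'     unfavorable class counted in pNeg;}
#'   \item{POS}{nonsynonymous with a BLOSUM62 score of zero or more;}
#'   \item{UNKNOWN}{the codon contains the ambiguity base N; excluded from
#'     all counts.}
#' }
#' A SNP overlapping k ORFs yields k independent effects (each ORF is scored
#' in its own frame, as required for overlapping and overprinted genes).
#'
#' @param snps SNP data.frame ([callSnps()] / [readSnpVcf()] layout).
#' @param orfs ORF data.frame from [findOrfs()].
#' @param genome A [GenomeRecord-class]. Each SNP's reference allele must
#'   match the genome base at its position; a mismatch is an error (it
#'   signals a VCF produced against a different reference).
#' @param code A [geneticCode()] list.
#' @param matrix Scoring matrix (default [blosum62()]).
#' @return data.frame with one row per (alt allele, ORF) pair: `orf_id`,
#'   `genome_pos` (1-based), `ref_allele`, `alt_allele` (forward strand),
#'   `strand`, `orf_offset`, `codon_index`, `codon_pos` (0-based in ORF
#'   orientation), `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `blosum_score` (NA for STOP/UNKNOWN), `category`.
#' @export
classifyEffects <- function(snps, orfs, genome, code = geneticCode(1),
                            matrix = blosum62()) {
  alleles <- .expandSnpAlleles(snps)
  L <- length(genome)
  gchars <- strsplit(genomeSeq(genome), "", fixed = TRUE)[[1]]
  if (nrow(alleles)) {
    mism <- gchars[alleles$pos] != alleles$ref
    if (any(mism)) {
      w <- which(mism)[1]
      stop("SNP reference allele mismatch at position ", alleles$pos[w],
           ": VCF says ", alleles$ref[w], ", genome has ",
           gchars[alleles$pos[w]],
           " (variants were likely called against a different reference)")
    }
  }
  out <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    if (!nrow(alleles)) next
    off <- orfOffset(alleles$pos, orf, L)
    sel <- which(!is.na(off))
    if (!length(sel)) next
    oseq <- .orfSequence(orf, gchars)
    off <- off[sel]
    ci <- off %/% 3L
    cp <- off %% 3L
    refCodon <- substring(oseq, ci * 3L + 1L, ci * 3L + 3L)
    orient <- function(b) if (orf$strand == "-") .complement(b) else b
    refA <- orient(alleles$ref[sel])
    altA <- orient(alleles$alt[sel])
    altCodon <- refCodon
    substr(altCodon, cp + 1L, cp + 1L) <- altA
    refAa <- unname(code$codons[refCodon])
    refAa[is.na(refAa) | grepl("N", refCodon, fixed = TRUE)] <- "X"
    altAa <- unname(code$codons[altCodon])
    altAa[is.na(altAa) | grepl("N", altCodon, fixed = TRUE)] <- "X"
    unknown <- refAa == "X" | altAa == "X"
    syn <- !unknown & refAa == altAa & refAa != "*"
    stp <- !unknown & !syn & xor(refAa == "*", altAa == "*")
    score <- rep(NA_integer_, length(sel))
    rest <- !unknown & !syn & !stp
    if (any(rest))
      score[rest] <- matrix[cbind(refAa[rest], altAa[rest])]
    if (any(syn))
      score[syn] <- matrix[cbind(refAa[syn], altAa[syn])]
    category <- rep("UNKNOWN", length(sel))
    category[syn] <- "SYN"
    category[stp] <- "STOP"
    category[rest & score < 0] <- "NEG"
    category[rest & score >= 0] <- "POS"
    out[[i]] <- data.frame(
      orf_id = orf$orf_id, genome_pos = alleles$pos[sel],
      ref_allele = alleles$ref[sel], alt_allele = alleles$alt[sel],
      strand = orf$strand, orf_offset = off, codon_index = ci,
      codon_pos = cp, ref_codon = refCodon, alt_codon = altCodon,
      ref_aa = refAa, alt_aa = altAa,
      blosum_score = ifelse(stp | unknown, NA_integer_, score),
      category = category, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyEffectFrame())
  res <- do.call(rbind, out)
  res <- res[order(res$orf_id, res$genome_pos, res$alt_allele), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.emptyEffectFrame <- function() {
  data.frame(orf_id = character(), genome_pos = integer(),
             ref_allele = character(), alt_allele = character(),
             strand = character(), orf_offset = integer(),
             codon_index = integer(), codon_pos = integer(),
             ref_codon = character(), alt_codon = character(),
             ref_aa = character(), alt_aa = character(),
             blosum_score = integer(), category = character(),
             stringsAsFactors = FALSE)
}

#' Per-ORF selection statistics
#'
#' Aggregates the classified effects into per-ORF counts and the two
#' selection ratios: `pn_ps` = (POS + NEG + STOP) / SYN and `pneg_ps` =
#' (NEG + STOP) / SYN. Stop gains and losses count on the unfavorable side
#' of both ratios. Ratios are plain count ratios: a zero denominator with a
#' positive numerator gives `Inf`, 0/0 gives `NA`. The same pNeg/pS ratio is
#' also computed over the first `first_nt` nucleotides of the ORF (in ORF
#' orientation, from the first base of the start codon), which feeds the
#' erroneous-start diagnostic. ORFs with fewer than `min_snps` classified
#' (non-UNKNOWN) effects are flagged `insufficient_data`.
#'
#' @param orfs ORF data.frame from [findOrfs()].
#' @param effects Effect data.frame from [classifyEffects()].
#' @param first_nt Width of the 5' window for the start diagnostic
#'   (default 50).
#' @param min_snps Minimum classified effects for an informative ORF
#'   (default 4).
#' @param pseudocount Optional pseudocount added to numerator and
#'   denominator of both ratios (default 0, plain ratios).
#' @return data.frame with one row per ORF: coordinates, counts `n_syn`,
#'   `n_pos`, `n_neg`, `n_stop`, `n_unknown`, ratios `pn_ps`, `pneg_ps`,
#'   `n_snps_first50`, `first50_pneg_ps`, and a `flags` string.
#' @export
computeOrfStats <- function(orfs, effects, first_nt = 50L, min_snps = 4L,
                            pseudocount = 0) {
  n <- nrow(orfs)
  cnt <- function(sel, cat) if (!length(sel)) 0L else
    sum(effects$category[sel] == cat)
  stats <- orfs[c("orf_id", "start", "end", "strand", "frame", "wraps",
                  "length_nt")]
  for (cc in c("n_syn", "n_pos", "n_neg", "n_stop", "n_unknown",
               "n_snps_first50"))
    stats[[cc]] <- integer(n)
  for (cc in c("pn_ps", "pneg_ps", "first50_pneg_ps"))
    stats[[cc]] <- rep(NA_real_, n)
  stats$flags <- character(n)
  byOrf <- split(seq_len(nrow(effects)), effects$orf_id)
  for (i in seq_len(n)) {
    sel <- byOrf[[orfs$orf_id[i]]]
    ns <- cnt(sel, "SYN"); np <- cnt(sel, "POS"); ng <- cnt(sel, "NEG")
    nt <- cnt(sel, "STOP"); nu <- cnt(sel, "UNKNOWN")
    stats$n_syn[i] <- ns; stats$n_pos[i] <- np; stats$n_neg[i] <- ng
    stats$n_stop[i] <- nt; stats$n_unknown[i] <- nu
    stats$pn_ps[i] <- .countRatio(np + ng + nt + pseudocount,
                                  ns + pseudocount)
    stats$pneg_ps[i] <- .countRatio(ng + nt + pseudocount, ns + pseudocount)
    f50 <- sel[effects$orf_offset[sel] < first_nt &
                 effects$category[sel] != "UNKNOWN"]
    stats$n_snps_first50[i] <- length(f50)
    ns5 <- sum(effects$category[f50] == "SYN")
    ng5 <- sum(effects$category[f50] %in% c("NEG", "STOP"))
    stats$first50_pneg_ps[i] <- .countRatio(ng5 + pseudocount,
                                            ns5 + pseudocount)
    if (ns + np + ng + nt < min_snps)
      stats$flags[i] <- .addFlag(stats$flags[i], "insufficient_data")
  }
  rownames(stats) <- NULL
  stats
}

#' Windowed substitution-category counts
#'
#' Partitions the genome into consecutive non-overlapping windows (the last
#' window may be short) and counts classified effects per
#' (strand, category group, window), with the three category groups SYN,
#' POS and NEG+STOP -- the six series of the report's bar charts (three per
#' strand). UNKNOWN effects are excluded. An effect is placed in the window
#' of its genomic position and on the strand of its ORF.
#'
#' @param effects Effect data.frame from [classifyEffects()].
#' @param genome_length Genome length in nucleotides.
#' @param window_nt Window width (default 15).
#' @return data.frame grid of `window` (1-based index), `start`, `end`,
#'   `strand`, `group` (`SYN`, `POS`, `NEGSTOP`) and `count`.
#' @export
windowCategoryCounts <- function(effects, genome_length, window_nt = 15L) {
  if (window_nt < 1L) stop("window_nt must be >= 1")
  nw <- ceiling(genome_length / window_nt)
  grid <- expand.grid(window = seq_len(nw), strand = c("+", "-"),
                      group = c("SYN", "POS", "NEGSTOP"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$start <- (grid$window - 1L) * window_nt + 1L
  grid$end <- pmin(grid$window * window_nt, genome_length)
  grid$count <- 0L
  keep <- effects$category != "UNKNOWN"
  if (any(keep)) {
    w <- (effects$genome_pos[keep] - 1L) %/% window_nt + 1L
    grp <- ifelse(effects$category[keep] == "SYN", "SYN",
                  ifelse(effects$category[keep] == "POS", "POS", "NEGSTOP"))
    key <- paste(w, effects$strand[keep], grp)
    tab <- table(key)
    gkey <- paste(grid$window, grid$strand, grid$group)
    hit <- match(gkey, names(tab))
    grid$count <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  grid[c("window", "start", "end", "strand", "group", "count")]
}
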