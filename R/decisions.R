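#' Decision thresholds for candidate selection
#'
#' Bundles the thresholds of the three decision rules. `candidate_max_ratio`
#' is the pNeg/pS ceiling for a protein-coding candidate (default 1.0);
#' ORFs between that and `overprint_max_ratio` (default 1.5) that overlap a
#' candidate in another frame or strand are flagged as possible overprinted
#' genes, whose substitution spectrum is constrained by the ancestral gene.
#' `start_fold` (default 2.0) and `first_nt` (default 50) drive the
#' erroneous-start diagnostic, with `min_first50_snps` (default 3)
#' classified effects required in the 5' window before the flag can fire.
#' `containment_frac` (default 0.9) is the fraction of a smaller candidate
#' that must be covered by a larger opposite-strand candidate for the
#' mirror-artifact discard.
#'
#' @param candidate_max_ratio,overprint_max_ratio,start_fold,first_nt,containment_frac,min_first50_snps
#'   See description.
#' @return A named list of class `DecisionConfig`.
#' @export
decisionConfig <- function(candidate_max_ratio = 1.0,
                           overprint_max_ratio = 1.5,
                           start_fold = 2.0, first_nt = 50L,
                           containment_frac = 0.9,
                           min_first50_snps = 3L) {
  stopifnot(candidate_max_ratio > 0,
            overprint_max_ratio >= candidate_max_ratio,
            start_fold > 1,
            containment_frac > 0, containment_frac <= 1,
            first_nt >= 1, min_first50_snps >= 0)
  structure(list(candidate_max_ratio = candidate_max_ratio,
                 overprint_max_ratio = overprint_max_ratio,
                 start_fold = start_fold, first_nt = as.integer(first_nt),
                 containment_frac = containment_frac,
                 min_first50_snps = as.integer(min_first50_snps)),
            class = "DecisionConfig")
}

#' Flag coding candidates and possible overprinted genes
#'
#' An ORF is a `candidate` when its pNeg/pS is at most
#' `candidate_max_ratio` and it is not flagged `insufficient_data`
#' (undefined or infinite ratios never qualify). An ORF is an
#' `overprint_candidate` when its ratio lies in
#' (`candidate_max_ratio`, `overprint_max_ratio`] and it overlaps a
#' candidate ORF in a different frame or strand -- the configuration in
#' which the ancestral gene inflates the ratio of an overprinted gene.
#'
#' @param stats Per-ORF statistics from [computeOrfStats()].
#' @param genome_length Genome length (for circular overlap arithmetic).
#' @param cfg A [decisionConfig()].
#' @return `stats` with updated `flags`.
#' @export
flagCandidates <- function(stats, genome_length, cfg = decisionConfig()) {
  r <- stats$pneg_ps
  insuff <- .hasFlag(stats$flags, "insufficient_data")
  cand <- !is.na(r) & is.finite(r) & r <= cfg$candidate_max_ratio & !insuff
  for (i in which(cand))
    stats$flags[i] <- .addFlag(stats$flags[i], "candidate")
  over <- !is.na(r) & is.finite(r) & r > cfg$candidate_max_ratio &
    r <= cfg$overprint_max_ratio & !insuff
  for (i in which(over)) {
    hit <- FALSE
    for (j in which(cand)) {
      if (stats$strand[i] == stats$strand[j] &&
          stats$frame[i] == stats$frame[j]) next
      if (.overlapLength(stats[i, ], stats[j, ], genome_length) > 0L) {
        hit <- TRUE; break
      }
    }
    if (hit)
      stats$flags[i] <- .addFlag(stats$flags[i], "overprint_candidate")
  }
  stats
}

#' Discard mirror-artifact candidates on the opposite strand
#'
#' Synonymous changes concentrate at third codon positions, so a true gene
#' imprints an apparently constrained ORF on one frame of the complementary
#' strand. A candidate ORF B is therefore discarded (`mirror_discarded`,
#' losing its `candidate` flag) when a surviving candidate ORF A on the
#' opposite strand is longer than B and covers at least `containment_frac`
#' of B. ORFs are examined from longest to shortest, so an ORF discarded by
#' a larger mirror cannot itself discard others; the filter is idempotent.
#' Equal-length mutual overlaps are broken deterministically: the ORF with
#' the higher pNeg/pS is discarded, and on a ratio tie the minus-strand one.
#'
#' @param stats Per-ORF statistics with candidate flags
#'   (see [flagCandidates()]).
#' @param genome_length Genome length.
#' @param cfg A [decisionConfig()].
#' @return `stats` with `mirror_discarded` flags and a `shadowed_by` column
#'   naming the shadowing ORF (NA otherwise).
#' @export
mirrorFilter <- function(stats, genome_length, cfg = decisionConfig()) {
  if (is.null(stats$shadowed_by))
    stats$shadowed_by <- rep(NA_character_, nrow(stats))
  cand <- which(.hasFlag(stats$flags, "candidate"))
  if (length(cand) < 2L) return(stats)
  # longest first; ties by lower ratio, then plus strand, then id
  ratio <- stats$pneg_ps[cand]
  ord <- order(-stats$length_nt[cand], ratio,
               stats$strand[cand] != "+", stats$orf_id[cand])
  cand <- cand[ord]
  alive <- rep(TRUE, length(cand))
  for (bi in seq_along(cand)) {
    b <- cand[bi]
    for (ai in seq_len(bi - 1L)) {
      if (!alive[ai]) next
      a <- cand[ai]
      if (stats$strand[a] == stats$strand[b]) next
      longer <- stats$length_nt[a] > stats$length_nt[b] ||
        (stats$length_nt[a] == stats$length_nt[b] &&
           (stats$pneg_ps[a] < stats$pneg_ps[b] ||
              (stats$pneg_ps[a] == stats$pneg_ps[b] &&
                 stats$strand[a] == "+")))
      if (!longer) next
      ov <- .overlapLength(stats[a, ], stats[b, ], genome_length)
      if (ov >= cfg$containment_frac * stats$length_nt[b]) {
        alive[bi] <- FALSE
        stats$flags[b] <- .addFlag(.dropFlag(stats$flags[b], "candidate"),
                                   "mirror_discarded")
        stats$shadowed_by[b] <- stats$orf_id[a]
        break
      }
    }
  }
  stats
}

#' Flag ORFs with a suspect start position
#'
#' When an ORF's true start codon lies downstream of its detected one, the
#' 5' stretch is noncoding and accumulates unfavorable substitutions. The
#' `suspect_start` flag fires when the pNeg/pS of the first `first_nt`
#' nucleotides is at least `start_fold` times the whole-ORF pNeg/pS, both
#' ratios are finite and defined, the whole-ORF ratio is positive, and at
#' least `min_first50_snps` classified effects support the 5' window.
#'
#' @param stats Per-ORF statistics from [computeOrfStats()].
#' @param cfg A [decisionConfig()].
#' @return `stats` with `suspect_start` flags.
#' @export
flagSuspectStart <- function(stats, cfg = decisionConfig()) {
  r <- stats$pneg_ps
  r5 <- stats$first50_pneg_ps
  hit <- !is.na(r) & is.finite(r) & r > 0 &
    !is.na(r5) & is.finite(r5) &
    r5 >= cfg$start_fold * r &
    stats$n_snps_first50 >= cfg$min_first50_snps
  for (i in which(hit))
    stats$flags[i] <- .addFlag(stats$flags[i], "suspect_start")
  stats
}
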