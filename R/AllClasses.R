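#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#' @importClassesFrom Biostrings DNAString
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' Reference genome with topology
#'
#' Container for a single reference sequence onto which microdiversity
#' evidence (reads or closely related sequences) has been, or will be,
#' mapped. The `circular` flag controls whether reading frames and ORFs may
#' continue across the origin.
#'
#' @slot id Sequence identifier (non-empty).
#' @slot sequence A [Biostrings::DNAString] over the alphabet A, C, G, T, N
#'   (uppercase).
#' @slot circular Logical; `TRUE` for circular genomes.
#'
#' @seealso [readGenome()], [GenomeRecord()]
#' @export
setClass("GenomeRecord",
  representation(id = "character", sequence = "DNAString", circular = "logical"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("illegal character ", paste(bad, collapse = ","),
                         " in sequence (alphabet is A,C,G,T,N)"))
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param id Sequence identifier.
#' @param sequence Character string or [Biostrings::DNAString]; lowercase is
#'   accepted and normalized to uppercase. Characters outside A,C,G,T,N are
#'   rejected.
#' @param circular Logical topology flag.
#' @return A [GenomeRecord-class] object.
#' @examples
#' g <- GenomeRecord("g", "acgt", circular = FALSE)
#' genomeSeq(g)
#' @export
GenomeRecord <- function(id, sequence, circular = FALSE) {
  s <- toupper(as.character(sequence))
  new("GenomeRecord", id = as.character(id), sequence = DNAString(s),
      circular = isTRUE(circular))
}

#' Full analysis result container
#'
#' Holds every intermediate and final table of a microdiversity analysis:
#' the genome, the ORF set, the SNP calls, the per-(SNP allele x ORF)
#' substitution effects, the per-ORF selection statistics with decision
#' flags, the windowed category counts and (when alignments were the
#' evidence) the coverage profile. Accessors: [orfTable()], [snpCalls()],
#' [effectTable()], [orfStats()], [windowCounts()], [coverageVector()],
#' [mirrorTable()].
#'
#' @slot genome A [GenomeRecord-class].
#' @slot orfs data.frame of ORFs (see [findOrfs()]).
#' @slot snps data.frame of SNP calls (see [callSnps()]).
#' @slot effects data.frame of substitution effects (see [classifyEffects()]).
#' @slot stats data.frame of per-ORF statistics and flags.
#' @slot windows data.frame of windowed category counts.
#' @slot mirrors data.frame of mirror (shadowed, shadowing) ORF pairs.
#' @slot coverage numeric per-position depth, or empty when evidence was a VCF.
#' @slot params list of the effective parameters of the run.
#' @export
setClass("MicrodivResult",
  representation(genome = "GenomeRecord", orfs = "data.frame",
                 snps = "data.frame", effects = "data.frame",
                 stats = "data.frame", windows = "data.frame",
                 mirrors = "data.frame", coverage = "numeric",
                 params = "list"))

setValidity("MicrodivResult", function(object) {
  msg <- character()
  if (nrow(object@stats) != nrow(object@orfs))
    msg <- c(msg, "one stats row per ORF required")
  if (length(object@coverage) &&
      length(object@coverage) != length(object@genome@sequence))
    msg <- c(msg, "coverage length must equal genome length")
  if (length(msg)) msg else TRUE
})
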