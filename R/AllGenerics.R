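#' @include AllClasses.R
NULL

#' Accessors for GenomeRecord and MicrodivResult
#'
#' `genomeId`, `genomeSeq` and `isCircular` read the slots of a
#' [GenomeRecord-class]. `orfTable`, `snpCalls`, `effectTable`, `orfStats`,
#' `windowCounts`, `mirrorTable` and `coverageVector` read the tables of a
#' [MicrodivResult-class].
#'
#' @param x A `GenomeRecord` or `MicrodivResult`.
#' @return The slot content; tables are plain `data.frame`s.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setGeneric("orfTable", function(x) standardGeneric("orfTable"))
#' @rdname accessors
#' @export
setGeneric("snpCalls", function(x) standardGeneric("snpCalls"))
#' @rdname accessors
#' @export
setGeneric("effectTable", function(x) standardGeneric("effectTable"))
#' @rdname accessors
#' @export
setGeneric("orfStats", function(x) standardGeneric("orfStats"))
#' @rdname accessors
#' @export
setGeneric("windowCounts", function(x) standardGeneric("windowCounts"))
#' @rdname accessors
#' @export
setGeneric("mirrorTable", function(x) standardGeneric("mirrorTable"))
#' @rdname accessors
#' @export
setGeneric("coverageVector", function(x) standardGeneric("coverageVector"))

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) as.character(x@sequence))
#' @rdname accessors
#' @export
setMethod("isCircular", "GenomeRecord", function(x) x@circular)

#' @describeIn accessors Genome length in nucleotides.
#' @export
setMethod("length", "GenomeRecord", function(x) length(x@sequence))

#' @rdname accessors
#' @export
setMethod("orfTable", "MicrodivResult", function(x) x@orfs)
#' @rdname accessors
#' @export
setMethod("snpCalls", "MicrodivResult", function(x) x@snps)
#' @rdname accessors
#' @export
setMethod("effectTable", "MicrodivResult", function(x) x@effects)
#' @rdname accessors
#' @export
setMethod("orfStats", "MicrodivResult", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("windowCounts", "MicrodivResult", function(x) x@windows)
#' @rdname accessors
#' @export
setMethod("mirrorTable", "MicrodivResult", function(x) x@mirrors)
#' @rdname accessors
#' @export
setMethod("coverageVector", "MicrodivResult", function(x) x@coverage)
#' @rdname accessors
#' @export
setMethod("genomeId", "MicrodivResult", function(x) x@genome@id)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord '", object@id, "': ", length(object@sequence), " nt, ",
      if (object@circular) "circular" else "linear", "\n", sep = "")
})

setMethod("show", "MicrodivResult", function(object) {
  st <- object@stats
  cat("MicrodivResult on ", object@genome@id, " (",
      length(object@genome@sequence), " nt, ",
      if (object@genome@circular) "circular" else "linear", ")\n", sep = "")
  cat("  ORFs: ", nrow(object@orfs),
      " | SNPs: ", nrow(object@snps),
      " | effects: ", nrow(object@effects), "\n", sep = "")
  if (nrow(st)) {
    nflag <- function(f) sum(vapply(st$flags, function(x) f %in%
                                      .splitFlags(x), logical(1)))
    cat("  candidates: ", nflag("candidate"),
        " | overprint: ", nflag("overprint_candidate"),
        " | mirror-discarded: ", nflag("mirror_discarded"),
        " | suspect start: ", nflag("suspect_start"), "\n", sep = "")
  }
})
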