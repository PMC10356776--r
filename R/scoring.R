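#' BLOSUM62 amino-acid substitution matrix
#'
#' The standard NCBI BLOSUM62 scores over the 20 amino acids plus the
#' ambiguity letters B, Z, X and the stop symbol `*`, embedded as a package
#' constant so that substitution-effect classification needs no external
#' matrix file. Positive scores mark biochemically tolerated replacements;
#' negative scores mark unfavorable ones, the class that drives the pNeg/pS
#' statistic.
#'
#' @return A symmetric 24 x 24 integer matrix with dimnames
#'   `ARNDCQEGHILKMFPSTWYVBZX*`.
#' @examples
#' blosum62()["D", "E"]  # conservative acidic swap, +2
#' blosum62()["L", "P"]  # disruptive, -3
#' @export
blosum62 <- function() .BLOSUM62

.blosumLetters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                    "F","P","S","T","W","Y","V","B","Z","X","*")

.BLOSUM62 <- matrix(c(
   4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4,
  -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4,
  -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4,
  -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4,
   0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4,
  -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4,
  -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4,
   0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4,
  -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4,
  -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4,
  -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4,
  -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4,
  -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4,
  -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4,
   1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4,
   0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4,
  -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4,
   0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4,
  -2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4,
  -1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4,
   0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4,
  -4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1),
  nrow = 24, byrow = TRUE,
  dimnames = list(.blosumLetters, .blosumLetters))

#' Read a substitution matrix in NCBI text format
#'
#' Parses a whitespace-delimited scoring matrix file as distributed by NCBI
#' (a header row of residue letters, then one labelled row per residue;
#' `#` comment lines ignored). Useful to swap BLOSUM62 for another matrix.
#'
#' @param path Path to the matrix file.
#' @return A symmetric integer matrix with residue dimnames.
#' @export
readScoringMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a scoring matrix: ", path)
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(cols))))
  dimnames(vals) <- list(rn, cols)
  if (!isTRUE(all.equal(vals[cols, cols], t(vals[cols, cols]))))
    stop("scoring matrix is not symmetric: ", path)
  vals
}

#' Genetic code table
#'
#' Wraps the NCBI genetic code tables shipped with Biostrings into the
#' small structure used by the ORF finder and the effect classifier: the 64
#' codon-to-amino-acid map (stops as `*`) plus the set of start codons used
#' for ORF detection. By default only ATG is treated as a start, which keeps
#' ORF start positions well defined for the first-50-nt start diagnostic;
#' alternative initiation codons of the table can be enabled.
#'
#' @param table NCBI translation table number (1 = standard, 11 = bacterial).
#' @param start_codons Character vector of start codons (default `"ATG"`).
#' @return A list with elements `table_id`, `codons` (named character vector
#'   of length 64) and `start_codons`.
#' @examples
#' geneticCode(1)$codons[c("ATG", "TAA")]
#' @export
geneticCode <- function(table = 1, start_codons = "ATG") {
  codons <- Biostrings::getGeneticCode(as.character(table))
  attributes(codons) <- list(names = names(codons))
  stopifnot(length(codons) == 64L, any(codons == "*"))
  list(table_id = as.integer(table), codons = codons,
       start_codons = toupper(start_codons))
}

#' Translate a DNA string
#'
#' Codon-by-codon translation under a [geneticCode()] table. Codons
#' containing the ambiguity base N translate to `X`; stop codons to `*`.
#'
#' @param dna DNA string whose length is a multiple of 3.
#' @param code A [geneticCode()] list.
#' @return Amino-acid string.
#' @examples
#' translateDna("ATGAAATAG")  # "MK*"
#' translateDna("ATGNAA")     # "MX"
#' @export
translateDna <- function(dna, code = geneticCode(1)) {
  dna <- toupper(as.character(dna))
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("length not a multiple of 3: ", n)
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  cods <- substring(dna, starts, starts + 2L)
  aa <- unname(code$codons[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
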