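#' Simulation configuration
#'
#' Describes a synthetic study: a random genome with planted protein-coding
#' genes, and a population of haplotypes diverged from it under purifying
#' selection inside the genes and neutrally outside. The population stands
#' in for mapped metagenomic reads or closely related database sequences;
#' haplotypes are full length and ungapped (substitution-only evolution), so
#' every difference from the reference is a candidate SNP.
#'
#' Default conditions: a 3000-nt genome with two 600-nt genes on opposite
#' strands, 200 haplotypes, a per-site proposal rate of 0.05 per haplotype
#' and a nonsynonymous acceptance probability (`omega`) of 0.1;
#' stop-introducing or stop-removing proposals inside genes are rejected
#' (`stop_acceptance` 0). Each planted gene starts with ATG, ends with a
#' stop, contains no internal in-frame stop, and is preceded (in its own
#' frame and strand) by a guard stop codon so that the discovered ORF start
#' coincides with the planted start. `extension_nt` plants an in-frame
#' stop-free stretch beginning with ATG immediately upstream of a gene:
#' the ORF finder then reports the ORF `extension_nt` too long, with the
#' extension evolving neutrally -- the erroneous-start scenario.
#'
#' @param genome_length Genome length in nt.
#' @param n_genes Number of planted genes (alternating strands), used when
#'   `gene_plan` is NULL.
#' @param gene_length Gene length in nt (multiple of 3, stop included).
#' @param gene_plan Optional explicit data.frame with columns `start`,
#'   `length`, `strand` and optionally `extension_nt`; overrides random
#'   placement. `start` is the 1-based forward-strand position of the
#'   gene's first base (its ATG for `+` genes).
#' @param n_haplotypes Population size.
#' @param per_site_mut_rate Per-site, per-haplotype substitution proposal
#'   probability.
#' @param omega Acceptance probability of nonsynonymous (non-stop)
#'   proposals inside genes.
#' @param stop_acceptance Acceptance probability of stop-gain/loss
#'   proposals inside genes.
#' @param extension_nt Noncoding in-frame 5' extension planted upstream of
#'   every gene (multiple of 3, default 0 = none).
#' @param seed Integer seed; every simulation output is a pure function of
#'   the configuration.
#' @return A named list of class `SimulationConfig`.
#' @export
simulationConfig <- function(genome_length = 3000L, n_genes = 2L,
                             gene_length = 600L, gene_plan = NULL,
                             n_haplotypes = 200L, per_site_mut_rate = 0.05,
                             omega = 0.1, stop_acceptance = 0,
                             extension_nt = 0L, seed = 1L) {
  if (gene_length %% 3L != 0L)
    stop("gene_length ", gene_length, " is not a codon multiple")
  if (extension_nt %% 3L != 0L)
    stop("extension_nt ", extension_nt, " is not a codon multiple")
  if (!is.null(gene_plan)) {
    if (any(gene_plan$length %% 3L != 0L))
      stop("gene_plan lengths must be codon multiples")
    if (is.null(gene_plan$extension_nt)) gene_plan$extension_nt <- 0L
    if (any(gene_plan$extension_nt %% 3L != 0L))
      stop("gene_plan extensions must be codon multiples")
  }
  stopifnot(per_site_mut_rate >= 0, per_site_mut_rate <= 1,
            omega >= 0, omega <= 1, stop_acceptance >= 0,
            stop_acceptance <= 1, n_haplotypes >= 1)
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 gene_plan = gene_plan,
                 n_haplotypes = as.integer(n_haplotypes),
                 per_site_mut_rate = per_site_mut_rate, omega = omega,
                 stop_acceptance = stop_acceptance,
                 extension_nt = as.integer(extension_nt),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.STOPS <- c("TAA", "TAG", "TGA")

.randomCodons <- function(n, exclude_stops = TRUE) {
  all <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste0), c("A", "C", "G", "T"), paste0))
  pool <- if (exclude_stops) setdiff(all, .STOPS) else all
  sample(pool, n, replace = TRUE)
}

#' Generate a reference genome with planted genes
#'
#' Builds a random background sequence and writes each planted gene (ATG,
#' stop-free body, terminal stop, upstream guard stop, optional noncoding
#' in-frame extension) into it at non-overlapping locations. Sets the RNG
#' seed from the configuration.
#'
#' @param cfg A [simulationConfig()].
#' @return A list with `genome` (a circular [GenomeRecord-class]) and
#'   `genes`, a data.frame with `gene_id`, `start`, `end`, `strand`,
#'   `extension_nt`, `ext_start` (coordinates of the gene proper; the
#'   extension lies 5' of `start` in gene orientation).
#' @export
generateReference <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$genome_length
  plan <- cfg$gene_plan
  if (is.null(plan)) {
    k <- cfg$n_genes
    span <- cfg$gene_length + cfg$extension_nt + 3L  # + guard stop
    gap <- (L - k * span) %/% (k + 1L)
    if (gap < 0L) stop("gene plan unsatisfiable in genome_length ", L)
    plan <- data.frame(
      start = vapply(seq_len(k), function(i)
        gap * i + span * (i - 1L) + 3L + cfg$extension_nt + 1L, integer(1)),
      length = rep(cfg$gene_length, k),
      strand = rep(c("+", "-"), length.out = k),
      extension_nt = rep(cfg$extension_nt, k),
      stringsAsFactors = FALSE)
  }
  if (any(plan$start + plan$length - 1L > L))
    stop("gene plan unsatisfiable in genome_length ", L)
  g <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  genes <- plan
  genes$gene_id <- sprintf("gene_%02d", seq_len(nrow(plan)))
  genes$end <- genes$start + genes$length - 1L
  genes$ext_start <- NA_integer_
  for (i in seq_len(nrow(genes))) {
    len <- genes$length[i]
    body <- c("ATG",
              .randomCodons(len / 3L - 2L),
              sample(.STOPS, 1L))
    ext <- genes$extension_nt[i]
    extCodons <- if (ext > 0L) c("ATG", .randomCodons(ext / 3L - 1L))
                 else character()
    # guard stop upstream of (extension +) gene, in gene frame
    block <- c(sample(.STOPS, 1L), extCodons, body)
    blockSeq <- paste(block, collapse = "")
    if (genes$strand[i] == "+") {
      from <- genes$start[i] - ext - 3L
      if (from < 1L) stop("gene plan unsatisfiable: no room for guard stop")
      g[from:(from + nchar(blockSeq) - 1L)] <-
        strsplit(blockSeq, "")[[1]]
      if (ext > 0L) genes$ext_start[i] <- genes$start[i] - ext
    } else {
      # gene orientation runs leftwards on the forward strand
      to <- genes$end[i] + ext + 3L
      if (to > L) stop("gene plan unsatisfiable: no room for guard stop")
      rc <- .revcomp(blockSeq)
      from <- to - nchar(blockSeq) + 1L
      g[from:to] <- strsplit(rc, "")[[1]]
      if (ext > 0L) genes$ext_start[i] <- genes$end[i] + ext
    }
  }
  genome <- GenomeRecord("sim_genome", paste(g, collapse = ""),
                         circular = TRUE)
  # overlap sanity on the same strand
  for (s in c("+", "-")) {
    gs <- genes[genes$strand == s, , drop = FALSE]
    if (nrow(gs) > 1L) {
      o <- order(gs$start)
      if (any(gs$start[o][-1] <= gs$end[o][-nrow(gs)]))
        stop("planted genes overlap on strand ", s)
    }
  }
  list(genome = genome,
       genes = genes[c("gene_id", "start", "end", "strand", "extension_nt",
                       "ext_start")])
}

# per-site x per-alt acceptance probabilities under the planted genes
.acceptanceMatrix <- function(genome, genes, cfg) {
  L <- length(genome)
  gchars <- strsplit(genomeSeq(genome), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  P <- matrix(1, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
  code <- geneticCode(1)
  for (i in seq_len(nrow(genes))) {
    orf <- list(start = genes$start[i], end = genes$end[i],
                strand = genes$strand[i], wraps = FALSE)
    posSeq <- genes$start[i]:genes$end[i]
    oseq <- .orfSequence(orf, gchars)
    for (pos in posSeq) {
      off <- orfOffset(pos, orf, L)
      ci <- off %/% 3L; cp <- off %% 3L
      refCodon <- substr(oseq, ci * 3L + 1L, ci * 3L + 3L)
      refAa <- code$codons[[refCodon]]
      for (b in bases) {
        if (b == gchars[pos]) next
        ob <- if (orf$strand == "-") .complement(b) else b
        altCodon <- refCodon
        substr(altCodon, cp + 1L, cp + 1L) <- ob
        altAa <- code$codons[[altCodon]]
        p <- if (altAa == refAa && refAa != "*") 1
             else if (xor(refAa == "*", altAa == "*")) cfg$stop_acceptance
             else if (refAa == "*" && altAa == "*") 1
             else cfg$omega
        P[b, pos] <- P[b, pos] * p  # overlapping genes: both must accept
      }
    }
  }
  P
}

#' Evolve a haplotype population from the reference
#'
#' Each haplotype proposes a substitution at every site independently with
#' probability `per_site_mut_rate` (alternate base uniform over the three
#' non-reference bases). Proposals in noncoding positions are always
#' accepted; proposals inside a planted gene are accepted with probability
#' 1 if synonymous, `omega` if nonsynonymous, `stop_acceptance` if they
#' gain or lose a stop. A site inside two genes must be accepted under
#' both (probabilities multiply). Proposals are evaluated against the
#' reference codon context, so sites are independent.
#'
#' @param genome A [GenomeRecord-class] from [generateReference()].
#' @param genes The planted-gene data.frame from [generateReference()].
#' @param cfg A [simulationConfig()].
#' @param seed Optional seed for this step alone (default: continue the
#'   current RNG stream).
#' @return Character vector of `n_haplotypes` full-length sequences.
#' @export
evolveHaplotypes <- function(genome, genes, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(genome)
  gchars <- strsplit(genomeSeq(genome), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  P <- .acceptanceMatrix(genome, genes, cfg)
  vapply(seq_len(cfg$n_haplotypes), function(h) {
    hap <- gchars
    sites <- which(stats::runif(L) < cfg$per_site_mut_rate)
    if (length(sites)) {
      altIdx <- sample.int(3L, length(sites), replace = TRUE)
      for (k in seq_along(sites)) {
        pos <- sites[k]
        alt <- setdiff(bases, gchars[pos])[altIdx[k]]
        if (stats::runif(1L) < P[alt, pos]) hap[pos] <- alt
      }
    }
    paste(hap, collapse = "")
  }, character(1))
}

# per-position base counts of a haplotype population (the generator's own
# truth pileup: depth = number of haplotypes everywhere)
.haplotypeCounts <- function(haplotypes, genome_length) {
  m <- matrix(unlist(strsplit(haplotypes, "", fixed = TRUE),
                     use.names = FALSE),
              nrow = genome_length)
  vapply(c("A", "C", "G", "T"), function(b) rowSums(m == b),
         numeric(genome_length))
}

#' Pileup columns of a haplotype population
#'
#' The generator-side equivalent of mapping every haplotype full length and
#' piling it up: depth equals the population size at every position.
#' Feeding the result to [callSnps()] yields the truth SNP set.
#'
#' @param haplotypes Character vector from [evolveHaplotypes()].
#' @param genome A [GenomeRecord-class].
#' @return Pileup data.frame as from [pileupColumns()].
#' @export
haplotypePileup <- function(haplotypes, genome) {
  L <- length(genome)
  cnt <- .haplotypeCounts(haplotypes, L)
  acgt <- rowSums(cnt)
  data.frame(pos = seq_len(L), depth = as.integer(acgt),
             A = as.integer(cnt[, "A"]), C = as.integer(cnt[, "C"]),
             G = as.integer(cnt[, "G"]), T = as.integer(cnt[, "T"]),
             stringsAsFactors = FALSE)
}

#' Write a SAM file of full-length ungapped haplotype alignments
#'
#' One primary record per haplotype: POS 1, MAPQ 60, CIGAR `<L>M`.
#'
#' @param haplotypes Character vector from [evolveHaplotypes()].
#' @param genome A [GenomeRecord-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
emitAlignments <- function(haplotypes, genome, path) {
  L <- length(genome)
  stopifnot(all(nchar(haplotypes) == L))
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", genomeId(genome), "\tLN:", L),
    sprintf("hap%04d\t0\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t*",
            seq_along(haplotypes), genomeId(genome), L, haplotypes))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the truth VCF of a haplotype population
#'
#' Lists every position at which an alternate base meets the pileup-caller
#' thresholds (defaults: 2 haplotypes and 1% of depth), with `INFO/DP` and
#' a single-sample `FORMAT/AD` field (reference count first).
#'
#' @param haplotypes Character vector from [evolveHaplotypes()].
#' @param genome A [GenomeRecord-class].
#' @param path Output path.
#' @param min_alt_reads,min_alt_frac Thresholds, as in [callSnps()].
#' @return The path, invisibly.
#' @export
emitTruthVcf <- function(haplotypes, genome, path, min_alt_reads = 2L,
                         min_alt_frac = 0.01) {
  pile <- haplotypePileup(haplotypes, genome)
  snps <- callSnps(pile, genome, min_alt_reads = min_alt_reads,
                   min_alt_frac = min_alt_frac)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", genomeId(genome), ",length=",
                  length(genome), ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "population", sep = "\t"))
  body <- character(0)
  if (nrow(snps)) {
    rowIdx <- match(snps$pos, pile$pos)
    refCount <- vapply(seq_len(nrow(snps)), function(i)
      as.integer(pile[rowIdx[i], snps$ref[i]]), integer(1))
    body <- vapply(seq_len(nrow(snps)), function(i) {
      paste(genomeId(genome), snps$pos[i], ".", snps$ref[i],
            paste(snps$alts[[i]], collapse = ","), ".", "PASS",
            paste0("DP=", snps$depth[i]), "AD",
            paste(c(refCount[i], snps$alt_counts[[i]]), collapse = ","),
            sep = "\t")
    }, character(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write reference, truth annotation and population files for one study
#'
#' Materializes a full simulated study on disk: reference FASTA, truth
#' gene GFF3, haplotype FASTA, SAM alignments, truth VCF, and a JSON
#' manifest recording the seed and every parameter.
#'
#' @param cfg A [simulationConfig()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list with the file paths (`reference`, `gff`,
#'   `haplotypes_fasta`, `sam`, `vcf`, `manifest`) plus the in-memory
#'   `genome`, `genes` and `haplotypes`.
#' @export
simulateMicrodiversity <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- generateReference(cfg)
  haps <- evolveHaplotypes(ref$genome, ref$genes, cfg)
  paths <- list(
    reference = file.path(outdir, "reference.fasta"),
    gff = file.path(outdir, "genes.gff3"),
    haplotypes_fasta = file.path(outdir, "haplotypes.fasta"),
    sam = file.path(outdir, "alignments.sam"),
    vcf = file.path(outdir, "truth.vcf"),
    manifest = file.path(outdir, "manifest.json"))
  .writeFastaLines(paths$reference,
                   setNames(genomeSeq(ref$genome), genomeId(ref$genome)))
  .writeTruthGff(paths$gff, ref$genome, ref$genes)
  .writeFastaLines(paths$haplotypes_fasta,
                   setNames(haps, sprintf("hap%04d", seq_along(haps))))
  emitAlignments(haps, ref$genome, paths$sam)
  emitTruthVcf(haps, ref$genome, paths$vcf)
  manifest <- cfg
  class(manifest) <- NULL
  manifest$gene_plan <- NULL
  manifest$genes <- ref$genes
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(genome = ref$genome, genes = ref$genes,
                          haplotypes = haps)))
}

.writeFastaLines <- function(path, seqs) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- unlist(lapply(names(seqs), function(n) {
    s <- seqs[[n]]
    starts <- seq.int(1L, nchar(s), by = 70L)
    c(paste0(">", n), substring(s, starts, pmin(starts + 69L, nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.writeTruthGff <- function(path, genome, genes) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("##gff-version 3",
             sprintf("%s\tMicroDiv_sim\tgene\t%d\t%d\t.\t%s\t0\tID=%s",
                     genomeId(genome), genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
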