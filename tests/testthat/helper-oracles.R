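# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results by per-position walking / whole-sequence
# editing, not by calling the package's vectorized scan paths.

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

randomGenome <- function(L, seed, circular = FALSE, id = "g") {
  set.seed(seed)
  GenomeRecord(id, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                         collapse = ""), circular = circular)
}

# Brute-force ORF enumeration: for every position on both strands, walk
# codon by codon to the next stop; keep, per terminating stop, the
# farthest-upstream start codon (start2stop) or the codon after the
# previous stop (stop2stop). Returns start/end/strand sorted.
oracleOrfs <- function(genome, min_len, mode = "start2stop") {
  L <- length(genome)
  circ <- isCircular(genome)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genomeSeq(genome) else rc(genomeSeq(genome))
    at <- function(p) {
      idx <- ((p - 1) %% L) + 1
      substr(s, idx, idx)
    }
    codonAt <- function(p) paste(at(p), at(p + 1), at(p + 2), collapse = "",
                                 sep = "")
    walkToStop <- function(p) {
      # returns oriented start of the terminating stop codon, or NA
      q <- p
      steps <- 0
      while (steps <= L %/% 3 + 2) {
        if (!circ && q + 2 > L) return(NA)
        if (codonAt(q) %in% stops) return(q)
        q <- q + 3
        steps <- steps + 1
      }
      NA
    }
    hits <- list()
    for (p in 1:L) {
      if (!circ && p + 2 > L) next
      cod <- codonAt(p)
      isAnchor <- if (mode == "start2stop") cod == "ATG"
                  else cod %in% stops
      if (!isAnchor) next
      q <- walkToStop(if (mode == "start2stop") p else p + 3)
      if (is.na(q)) next
      ostart <- if (mode == "start2stop") p else p + 3
      len <- q + 2 - ostart + 1
      if (len > L || len < 3) next
      hits[[length(hits) + 1]] <- c(ostart, q, len)
    }
    if (length(hits)) {
      m <- do.call(rbind, hits)
      # one ORF per terminating stop: the longest anchored stretch
      stopKey <- ((m[, 2] - 1) %% L) + 1
      keep <- unlist(lapply(split(seq_len(nrow(m)), stopKey), function(ix)
        ix[which.max(m[ix, 3])]))
      m <- m[keep, , drop = FALSE]
      for (r in seq_len(nrow(m))) {
        len <- m[r, 3]
        if (len < min_len) next
        os <- ((m[r, 1] - 1) %% L) + 1
        oe <- ((m[r, 2] + 2 - 1) %% L) + 1
        if (strand == "+") {
          st <- os; en <- oe
        } else {
          st <- L - oe + 1; en <- L - os + 1
        }
        out[[length(out) + 1]] <- data.frame(start = st, end = en,
                                             strand = strand,
                                             length_nt = len)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length_nt = integer()))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$start, df$strand, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Full-ORF-translation classification oracle: edit the substituted base
# into a copy of the whole genome, rebuild and translate the entire ORF
# from both genome versions, and diff the protein sequences.
oracleClassify <- function(pos, alt, orf, genome,
                           matrix = blosum62()) {
  L <- length(genome)
  gc <- Biostrings::getGeneticCode("1")
  orfDna <- function(gseq) {
    posSeq <- if (orf$wraps) c(orf$start:L, 1:orf$end) else orf$start:orf$end
    s <- paste(strsplit(gseq, "")[[1]][posSeq], collapse = "")
    if (orf$strand == "-") rc(s) else s
  }
  translate <- function(s) {
    n <- nchar(s)
    cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- unname(gc[cods])
    aa[is.na(aa) | grepl("N", cods)] <- "X"
    aa
  }
  gref <- genomeSeq(genome)
  galt <- gref
  substr(galt, pos, pos) <- alt
  aaRef <- translate(orfDna(gref))
  aaAlt <- translate(orfDna(galt))
  d <- which(aaRef != aaAlt)
  if (length(d) == 0) {
    # same protein: synonymous unless the (unchanged) codon is stop/N
    off <- if (orf$strand == "+") (pos - orf$start) %% L
           else (orf$end - pos) %% L
    ci <- off %/% 3 + 1
    if (aaRef[ci] == "X") return("UNKNOWN")
    if (aaRef[ci] == "*") return("POS")  # stop-to-stop scores +1
    return("SYN")
  }
  a <- aaRef[d[1]]; b <- aaAlt[d[1]]
  if (a == "X" || b == "X") return("UNKNOWN")
  if (xor(a == "*", b == "*")) return("STOP")
  if (matrix[a, b] < 0) "NEG" else "POS"
}

# minimal SAM writer for handcrafted alignment records
writeSam <- function(path, genomeId, genomeLen, records) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", genomeId, "\tLN:", genomeLen),
             vapply(records, function(r)
               paste(r$qname, r$flag, if (bitwAnd(r$flag, 4L) > 0) "*"
                     else genomeId,
                     r$pos, r$mapq, r$cigar, "*", 0, 0, r$seq, "*",
                     sep = "\t"), character(1)))
  writeLines(lines, path)
  path
}

samRec <- function(qname, pos, cigar, seq, flag = 0L, mapq = 60L) {
  list(qname = qname, flag = flag, pos = pos, mapq = mapq, cigar = cigar,
       seq = seq)
}

writeVcfLines <- function(path, body,
                          contig = "g", len = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(len)) paste0("##contig=<ID=", contig, ",length=",
                                     len, ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# stats row builder for decision-rule unit tests
statRow <- function(orf_id, start, end, strand, length_nt, pneg_ps,
                    first50 = NA_real_, n_first50 = 0L, frame = 0L,
                    wraps = FALSE, flags = "") {
  data.frame(orf_id = orf_id, start = start, end = end, strand = strand,
             frame = frame, wraps = wraps, length_nt = length_nt,
             n_syn = 10L, n_pos = 0L, n_neg = 0L, n_stop = 0L,
             n_unknown = 0L, n_snps_first50 = n_first50,
             pn_ps = pneg_ps, pneg_ps = pneg_ps,
             first50_pneg_ps = first50, flags = flags,
             stringsAsFactors = FALSE)
}

snpFrame <- function(pos, ref, alts, depth = 100L, alt_counts = NULL) {
  df <- data.frame(pos = pos, ref = ref, depth = depth,
                   stringsAsFactors = FALSE)
  df$alts <- I(alts)
  df$alt_counts <- I(if (is.null(alt_counts))
    lapply(alts, function(a) rep(5L, length(a))) else alt_counts)
  df
}
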