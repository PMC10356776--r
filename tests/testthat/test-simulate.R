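test_that("planted genes are well-formed and generation is deterministic", {
  cfg <- simulationConfig(genome_length = 3000L, n_genes = 2L,
                          gene_length = 600L, seed = 11L)
  ref <- generateReference(cfg)
  expect_equal(length(ref$genome), 3000L)
  expect_equal(nrow(ref$genes), 2L)
  gchars <- strsplit(genomeSeq(ref$genome), "")[[1]]
  for (i in 1:2) {
    orf <- list(start = ref$genes$start[i], end = ref$genes$end[i],
                strand = ref$genes$strand[i], wraps = FALSE)
    aa <- translateDna(MicroDiv:::.orfSequence(orf, gchars))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  ref2 <- generateReference(cfg)
  expect_identical(genomeSeq(ref$genome), genomeSeq(ref2$genome))
  expect_identical(ref$genes, ref2$genes)

  expect_error(simulationConfig(gene_length = 601L), "codon multiple")
  expect_error(generateReference(
    simulationConfig(genome_length = 500L, n_genes = 2L,
                     gene_length = 600L)), "unsatisfiable")
})

test_that("omega = 0 forbids amino-acid change inside genes", {
  cfg <- simulationConfig(genome_length = 1200L, n_genes = 1L,
                          gene_length = 300L, n_haplotypes = 30L,
                          per_site_mut_rate = 0.05, omega = 0,
                          stop_acceptance = 0, seed = 5L)
  ref <- generateReference(cfg)
  haps <- evolveHaplotypes(ref$genome, ref$genes, cfg)
  gene <- ref$genes[1, ]
  gchars <- strsplit(genomeSeq(ref$genome), "")[[1]]
  orf <- list(start = gene$start, end = gene$end, strand = gene$strand,
              wraps = FALSE)
  refAa <- translateDna(MicroDiv:::.orfSequence(orf, gchars))
  for (h in haps) {
    hc <- strsplit(h, "")[[1]]
    expect_identical(translateDna(MicroDiv:::.orfSequence(orf, hc)), refAa)
  }
})

test_that("neutral evolution (omega = 1) matches the enumeration expectation", {
  # with all proposals accepted, the realized SYN fraction of within-gene
  # differences approaches the fraction of synonymous changes among all
  # 9L possible single-base changes of the gene
  cfg <- simulationConfig(genome_length = 1500L, n_genes = 1L,
                          gene_length = 900L, n_haplotypes = 150L,
                          per_site_mut_rate = 0.05, omega = 1,
                          stop_acceptance = 1, seed = 23L)
  ref <- generateReference(cfg)
  gene <- ref$genes[1, ]
  gchars <- strsplit(genomeSeq(ref$genome), "")[[1]]
  orf <- list(start = gene$start, end = gene$end, strand = gene$strand,
              wraps = FALSE)
  code <- Biostrings::getGeneticCode("1")
  # exhaustive neutral expectation
  synCount <- 0L; totCount <- 0L
  oseq <- MicroDiv:::.orfSequence(orf, gchars)
  for (off in 0:(nchar(oseq) - 1)) {
    ci <- off %/% 3; cp <- off %% 3
    refCodon <- substr(oseq, ci * 3 + 1, ci * 3 + 3)
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(refCodon, cp + 1, cp + 1))) {
      altCodon <- refCodon
      substr(altCodon, cp + 1, cp + 1) <- b
      totCount <- totCount + 1L
      if (code[[refCodon]] == code[[altCodon]]) synCount <- synCount + 1L
    }
  }
  expected <- synCount / totCount
  haps <- evolveHaplotypes(ref$genome, ref$genes, cfg)
  nSyn <- 0L; nTot <- 0L
  for (h in haps) {
    hc <- strsplit(h, "")[[1]]
    diffs <- which(hc != gchars & seq_along(hc) >= gene$start &
                     seq_along(hc) <= gene$end)
    for (pos in diffs) {
      off <- orfOffset(pos, orf, length(ref$genome))
      ci <- off %/% 3; cp <- off %% 3
      refCodon <- substr(oseq, ci * 3 + 1, ci * 3 + 3)
      ob <- if (orf$strand == "-") chartr("ACGT", "TGCA", hc[pos]) else
        hc[pos]
      altCodon <- refCodon
      substr(altCodon, cp + 1, cp + 1) <- ob
      nTot <- nTot + 1L
      if (code[[refCodon]] == code[[altCodon]]) nSyn <- nSyn + 1L
    }
  }
  expect_gt(nTot, 1000L)
  expect_lt(abs(nSyn / nTot - expected), 0.05)
})

test_that("same seed reproduces haplotypes; different seeds differ", {
  cfg <- simulationConfig(genome_length = 900L, n_genes = 1L,
                          gene_length = 300L, n_haplotypes = 10L,
                          seed = 3L)
  ref <- generateReference(cfg)
  h1 <- evolveHaplotypes(ref$genome, ref$genes, cfg, seed = 99L)
  h2 <- evolveHaplotypes(ref$genome, ref$genes, cfg, seed = 99L)
  expect_identical(h1, h2)
  h3 <- evolveHaplotypes(ref$genome, ref$genes, cfg, seed = 100L)
  expect_false(identical(h1, h3))
})

test_that("identical haplotypes yield an empty truth VCF; planted minor alleles appear", {
  g <- GenomeRecord("g", strrep("ACGT", 25))
  haps <- rep(genomeSeq(g), 10)
  path <- withr::local_tempfile(fileext = ".vcf")
  emitTruthVcf(haps, g, path)
  snps <- readSnpVcf(path, quiet = TRUE)
  expect_equal(nrow(snps), 0L)
  # plant an alt in 2 of 200 haplotypes: exactly at the 2-read / 1% bar
  haps <- rep(genomeSeq(g), 200)
  substr(haps[1], 13, 13) <- "T"   # ref A -> T
  substr(haps[2], 13, 13) <- "T"
  emitTruthVcf(haps, g, path)
  snps <- readSnpVcf(path, quiet = TRUE)
  expect_equal(snps$pos, 13L)
  expect_equal(snps$alts[[1]], "T")
  expect_equal(snps$alt_counts[[1]], 2L)
  expect_equal(snps$depth[1], 200L)
})

test_that("emitted files round-trip through the package readers", {
  cfg <- simulationConfig(genome_length = 1200L, n_genes = 2L,
                          gene_length = 300L, n_haplotypes = 40L,
                          per_site_mut_rate = 0.03, seed = 31L)
  dir <- withr::local_tempdir()
  sim <- simulateMicrodiversity(cfg, dir)
  g <- readGenome(sim$reference, circular = TRUE)
  expect_identical(genomeSeq(g), genomeSeq(sim$genome))
  segs <- readAlignments(sim$sam, g, quiet = TRUE)
  expect_equal(nrow(segs), 40L)
  expect_identical(sort(segs$seq), sort(sim$haplotypes))
  genes <- readGeneFeatures(sim$gff, types = "gene")
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$start, sim$genes$start)
  manifest <- jsonlite::read_json(sim$manifest)
  expect_equal(manifest$seed, 31L)

  # end-to-end consistency: pileup + thresholds on the SAM equals the
  # truth VCF record set
  snpsSam <- callSnps(pileupColumns(segs, g), g)
  snpsVcf <- readSnpVcf(sim$vcf, quiet = TRUE)
  expect_equal(snpsSam$pos, snpsVcf$pos)
  expect_identical(unclass(snpsSam$alts), unclass(snpsVcf$alts),
                   ignore_attr = TRUE)
  expect_identical(unclass(snpsSam$alt_counts),
                   unclass(snpsVcf$alt_counts), ignore_attr = TRUE)
})

test_that("different simulation seeds give different populations", {
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  simA <- simulateMicrodiversity(
    simulationConfig(genome_length = 600L, n_genes = 1L,
                     gene_length = 150L, n_haplotypes = 5L, seed = 1L),
    dirA)
  simB <- simulateMicrodiversity(
    simulationConfig(genome_length = 600L, n_genes = 1L,
                     gene_length = 150L, n_haplotypes = 5L, seed = 2L),
    dirB)
  expect_false(identical(readLines(simA$haplotypes_fasta),
                         readLines(simB$haplotypes_fasta)))
})
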