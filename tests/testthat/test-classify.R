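test_that("codon-level classification matches the canonical examples", {
  # one plus-strand ORF: ATG GGA GAT CTG TGG TAG
  g <- GenomeRecord("g", "ATGGGAGATCTGTGGTAG")
  orfs <- findOrfs(g, min_orf_nt = 18)
  expect_equal(nrow(orfs), 1L)
  case <- function(pos, ref, alt) {
    eff <- classifyEffects(snpFrame(pos, ref, list(alt)), orfs, g)
    eff[1, ]
  }
  # GGA -> GGG, 4-fold degenerate third position
  e <- case(6L, "A", "G")
  expect_equal(e$category, "SYN")
  expect_equal(e$ref_aa, "G"); expect_equal(e$alt_aa, "G")
  expect_equal(e$codon_index, 1L); expect_equal(e$codon_pos, 2L)
  # GAT -> GAA gives D -> E, BLOSUM62 +2
  e <- case(9L, "T", "A")
  expect_equal(e$category, "POS")
  expect_equal(e$blosum_score, 2L)
  # CTG -> CCG gives L -> P, BLOSUM62 -3
  e <- case(11L, "T", "C")
  expect_equal(e$category, "NEG")
  expect_equal(e$blosum_score, -3L)
  # TGG -> TGA gives W -> stop
  e <- case(15L, "G", "A")
  expect_equal(e$category, "STOP")
  expect_true(is.na(e$blosum_score))
})

test_that("minus-strand SNPs are complemented into the ORF frame", {
  # forward CAT at 5..7 is ATG on the minus strand
  g <- GenomeRecord("g", "TTACCATTAA")
  orfs <- data.frame(orf_id = "o1", start = 5L, end = 7L, strand = "-",
                     frame = 0L, wraps = FALSE, length_nt = 3L,
                     source = "user", stringsAsFactors = FALSE)
  eff <- classifyEffects(snpFrame(6L, "A", list("G")), orfs, g)
  expect_equal(eff$ref_codon, "ATG")
  expect_equal(eff$alt_codon, "ACG")
  expect_equal(eff$ref_aa, "M"); expect_equal(eff$alt_aa, "T")
  expect_equal(eff$category, "NEG")
})

test_that("a stale reference allele is rejected with its position", {
  g <- GenomeRecord("g", "ATGAAATAG")
  orfs <- findOrfs(g, min_orf_nt = 9)
  expect_error(classifyEffects(snpFrame(4L, "C", list("G")), orfs, g),
               "position 4")
})

test_that("codons containing N classify as UNKNOWN and leave the counts", {
  g <- GenomeRecord("g", "ATGANATAG")
  orfs <- data.frame(orf_id = "o1", start = 1L, end = 9L, strand = "+",
                     frame = 0L, wraps = FALSE, length_nt = 9L,
                     source = "user", stringsAsFactors = FALSE)
  eff <- classifyEffects(snpFrame(4L, "A", list("C")), orfs, g)
  expect_equal(eff$category, "UNKNOWN")
  st <- computeOrfStats(orfs, eff)
  expect_equal(st$n_unknown, 1L)
  expect_equal(st$n_syn + st$n_pos + st$n_neg + st$n_stop, 0L)
  expect_true(is.na(st$pneg_ps))
})

test_that("single-codon classification equals the full-translation oracle", {
  n_checked <- 0L
  for (seed in 1:40) {
    g <- randomGenome(120L + seed %% 7L, seed = seed,
                      circular = seed %% 2L == 0L)
    orfs <- findOrfs(g, min_orf_nt = 30)
    if (!nrow(orfs)) next
    gchars <- strsplit(genomeSeq(g), "")[[1]]
    set.seed(1000 + seed)
    for (rep in 1:10) {
      i <- sample(nrow(orfs), 1)
      orf <- orfs[i, ]
      posSeq <- if (orf$wraps) c(orf$start:length(g), 1:orf$end)
                else orf$start:orf$end
      pos <- sample(posSeq, 1)
      ref <- gchars[pos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      eff <- classifyEffects(snpFrame(pos, ref, list(alt)), orfs[i, ], g)
      want <- oracleClassify(pos, alt, orf, g)
      expect_equal(eff$category, want,
                   info = sprintf("seed=%d pos=%d %s>%s orf=[%d,%d,%s]",
                                  seed, pos, ref, alt, orf$start, orf$end,
                                  orf$strand))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("strand symmetry: classification is invariant under reflection", {
  for (seed in 1:10) {
    g <- randomGenome(150L, seed = 200 + seed)
    L <- length(g)
    orfs <- findOrfs(g, min_orf_nt = 30)
    if (!nrow(orfs)) next
    gchars <- strsplit(genomeSeq(g), "")[[1]]
    set.seed(300 + seed)
    i <- sample(nrow(orfs), 1)
    orf <- orfs[i, ]
    pos <- sample(orf$start:orf$end, 1)
    ref <- gchars[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- classifyEffects(snpFrame(pos, ref, list(alt)), orfs[i, ], g)
    # reflect everything
    g2 <- reverseComplementGenome(g)
    orf2 <- orf
    orf2$start <- L - orf$end + 1L
    orf2$end <- L - orf$start + 1L
    orf2$strand <- if (orf$strand == "+") "-" else "+"
    pos2 <- L - pos + 1L
    eff2 <- classifyEffects(
      snpFrame(pos2, chartr("ACGT", "TGCA", ref),
               list(chartr("ACGT", "TGCA", alt))), orf2, g2)
    expect_equal(eff2$category, eff$category)
    expect_equal(eff2$blosum_score, eff$blosum_score)
    expect_equal(eff2$codon_index, eff$codon_index)
    expect_equal(eff2$codon_pos, eff$codon_pos)
  }
})

test_that("per-ORF ratios use plain counts with NA/Inf sentinels", {
  orfs <- data.frame(orf_id = "o1", start = 1L, end = 90L, strand = "+",
                     frame = 0L, wraps = FALSE, length_nt = 90L,
                     source = "user", stringsAsFactors = FALSE)
  mkEff <- function(categories, offsets = seq_along(categories) * 3L) {
    data.frame(orf_id = "o1", genome_pos = offsets + 1L,
               ref_allele = "A", alt_allele = "G", strand = "+",
               orf_offset = offsets, codon_index = offsets %/% 3L,
               codon_pos = offsets %% 3L, ref_codon = "AAA",
               alt_codon = "AAG", ref_aa = "K", alt_aa = "K",
               blosum_score = NA_integer_, category = categories,
               stringsAsFactors = FALSE)
  }
  st <- computeOrfStats(orfs, mkEff(c(rep("SYN", 10), rep("NEG", 5))))
  expect_equal(st$pneg_ps, 0.5)
  expect_equal(st$pn_ps, 0.5)
  st <- computeOrfStats(orfs, mkEff(rep("NEG", 3)))
  expect_equal(st$pneg_ps, Inf)
  st <- computeOrfStats(orfs, mkEff("SYN")[0, ])
  expect_true(is.na(st$pneg_ps))
  expect_match(st$flags, "insufficient_data")
  # STOP counts on the unfavorable side of both ratios
  st <- computeOrfStats(orfs, mkEff(c("SYN", "SYN", "STOP", "POS")))
  expect_equal(st$pneg_ps, 0.5)
  expect_equal(st$pn_ps, 1.0)
})

test_that("the first-50-nt ratio is restricted by ORF offset", {
  orfs <- data.frame(orf_id = "o1", start = 1L, end = 150L, strand = "+",
                     frame = 0L, wraps = FALSE, length_nt = 150L,
                     source = "user", stringsAsFactors = FALSE)
  eff <- data.frame(orf_id = "o1",
                    genome_pos = c(5L, 20L, 40L, 80L, 100L, 120L),
                    ref_allele = "A", alt_allele = "G", strand = "+",
                    orf_offset = c(4L, 19L, 39L, 79L, 99L, 119L),
                    codon_index = 0L, codon_pos = 0L, ref_codon = "AAA",
                    alt_codon = "GAA", ref_aa = "K", alt_aa = "E",
                    blosum_score = 1L,
                    category = c("NEG", "NEG", "SYN", "SYN", "SYN", "SYN"),
                    stringsAsFactors = FALSE)
  st <- computeOrfStats(orfs, eff, first_nt = 50L)
  expect_equal(st$n_snps_first50, 3L)
  expect_equal(st$first50_pneg_ps, 2)      # 2 NEG / 1 SYN in first 50 nt
  expect_equal(st$pneg_ps, 0.5)            # 2 NEG / 4 SYN overall
})

test_that("windowed counts place effects and conserve totals", {
  g <- GenomeRecord("g", strrep("A", 60))
  eff <- data.frame(orf_id = "o1", genome_pos = c(17L, 1L, 31L),
                    ref_allele = "A", alt_allele = "G",
                    strand = c("+", "-", "+"), orf_offset = 0L,
                    codon_index = 0L, codon_pos = 0L, ref_codon = "AAA",
                    alt_codon = "GAA", ref_aa = "K", alt_aa = "E",
                    blosum_score = 1L,
                    category = c("SYN", "NEG", "UNKNOWN"),
                    stringsAsFactors = FALSE)
  w <- windowCategoryCounts(eff, 60L, window_nt = 15L)
  expect_equal(nrow(w), 4L * 2L * 3L)
  expect_equal(w$count[w$window == 2 & w$strand == "+" & w$group == "SYN"],
               1L)
  expect_equal(w$count[w$window == 1 & w$strand == "-" &
                         w$group == "NEGSTOP"], 1L)
  # UNKNOWN excluded; totals conserve classified effects
  expect_equal(sum(w$count), sum(eff$category != "UNKNOWN"))
  # degenerate: no effects -> full all-zero grid
  w0 <- windowCategoryCounts(eff[0, ], 61L, window_nt = 15L)
  expect_equal(nrow(w0), 5L * 6L)
  expect_true(all(w0$count == 0L))
})

test_that("each alt of a multi-allelic SNP and each overlapping ORF counts", {
  g <- GenomeRecord("g", "ATGGGAGATCTGTGGTAG")
  orfs <- findOrfs(g, min_orf_nt = 18)
  orfs <- rbind(orfs, within(orfs, {
    orf_id <- "user_orf"; source <- "user"
  }))
  eff <- classifyEffects(snpFrame(6L, "A", list(c("G", "T"))), orfs, g)
  expect_equal(nrow(eff), 4L)  # 2 alts x 2 ORFs
  expect_setequal(unique(eff$orf_id), c("ORF_001", "user_orf"))
})
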