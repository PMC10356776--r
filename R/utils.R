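# Internal helpers shared across modules.

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(.complement(s), "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

.splitFlags <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
}

.addFlag <- function(x, flag) {
  f <- unique(c(.splitFlags(x), flag))
  paste(f, collapse = ",")
}

.dropFlag <- function(x, flag) {
  f <- setdiff(.splitFlags(x), flag)
  paste(f, collapse = ",")
}

.hasFlag <- function(x, flag) {
  vapply(x, function(v) flag %in% .splitFlags(v), logical(1), USE.NAMES = FALSE)
}

# count ratio with the sentinel semantics used throughout: x/0 -> Inf for
# x > 0, 0/0 -> NA
.countRatio <- function(num, den) {
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
}

# render a ratio for TSV output: 2 decimals, "NA", "Inf"
.fmtRatio <- function(x) {
  ifelse(is.na(x), "NA", ifelse(is.infinite(x), "Inf", sprintf("%.2f", x)))
}

# positions (1-based) covered by an interval that may wrap the origin
.coveredPositions <- function(start, end, wraps, L) {
  if (!wraps) start:end else c(start:L, 1:end)
}

# length of the overlap of two possibly wrapping intervals on a circle
.overlapLength <- function(a, b, L) {
  length(intersect(
    .coveredPositions(a$start, a$end, a$wraps, L),
    .coveredPositions(b$start, b$end, b$wraps, L)))
}

.emptySnpFrame <- function() {
  df <- data.frame(pos = integer(), ref = character(), depth = integer(),
                   stringsAsFactors = FALSE)
  df$alts <- I(list())
  df$alt_counts <- I(list())
  df
}

# expand a SNP frame (list columns alts/alt_counts) to one row per alt allele
.expandSnpAlleles <- function(snps) {
  if (!nrow(snps))
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      depth = integer(), alt_count = integer(),
                      stringsAsFactors = FALSE))
  k <- lengths(snps$alts)
  data.frame(
    pos = rep(snps$pos, k),
    ref = rep(snps$ref, k),
    alt = unlist(snps$alts, use.names = FALSE),
    depth = rep(snps$depth, k),
    alt_count = unlist(lapply(seq_len(nrow(snps)), function(i) {
      ac <- snps$alt_counts[[i]]
      if (is.null(ac)) rep(NA_integer_, k[i]) else as.integer(ac)
    }), use.names = FALSE),
    stringsAsFactors = FALSE)
}
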