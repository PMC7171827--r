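# Independent oracles and small fixture builders shared across tests.

# Longhand scalar transcription of the Weir & Cockerham (1984) two-population
# variance components, kept deliberately separate from the vectorized
# implementation: explicit per-population sums, no shared code.
wc_oracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]
  gB <- gB[!is.na(gB)]
  n <- c(length(gA), length(gB))
  if (any(n < 2)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  r <- 2
  p <- c(sum(gA) / (2 * n[1]), sum(gB) / (2 * n[2]))
  h <- c(sum(gA == 1) / n[1], sum(gB == 1) / n[2])
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Brute-force Saitou-Nei neighbor joining via the Q criterion, building a
# Newick string step by step; ties broken by row-major order.  Returns an
# unrooted ape::phylo.
nj_oracle <- function(d) {
  labs <- rownames(d)
  nwk <- labs
  D <- as.matrix(d)
  while (length(nwk) > 3) {
    n <- nrow(D)
    rs <- rowSums(D)
    best <- c(NA, NA)
    bestq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * D[i, j] - rs[i] - rs[j]
      if (q < bestq - 1e-12) {
        bestq <- q
        best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    node <- sprintf("(%s:%.10f,%s:%.10f)", nwk[i], li, nwk[j], lj)
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], node)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 nwk[1], l1, nwk[2], l2, nwk[3], l3)
  ape::read.tree(text = txt)
}

# Sequential all-pairs greedy LD pruning (no windowing): the reference for
# single-window toy matrices.
prune_oracle <- function(geno, r2_max) {
  kept <- integer(0)
  for (j in seq_len(nrow(geno))) {
    ok <- TRUE
    for (i in kept) {
      r <- suppressWarnings(
        stats::cor(geno[i, ], geno[j, ], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

# Mean pairwise difference over all haplotype pairs at one site.
pi_enum <- function(haps) {
  haps <- haps[!is.na(haps)]
  n <- length(haps)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + as.integer(haps[i] != haps[j])
  }
  tot / choose(n, 2)
}

# Independent linear-interpolation quantile (type 7), written longhand.
quantile_oracle <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q
  lo <- floor(h)
  if (lo + 2 > length(x)) return(x[length(x)])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Quick genotype-matrix builder for toy tables.
make_gm <- function(geno, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                    samples = NULL, haplo = NULL, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  genotype_matrix(chrom, pos, ref, alt, geno, samples, haplo = haplo,
                  chrom_lengths = chrom_lengths)
}

# A window_stat series over one toy window per value, for outlier tests.
make_stat <- function(values, chrom = "chr1", stat_name = "toy") {
  n <- length(values)
  ws <- list(windows = data.frame(chrom = chrom,
                                  start = (seq_len(n) - 1L) * 1000L,
                                  end = seq_len(n) * 1000L),
             size = 1000L, step = 1000L)
  out <- cbind(ws$windows, n_snps = rep(10L, n), value = values)
  attr(out, "stat_name") <- stat_name
  class(out) <- c("window_stat", "data.frame")
  out
}

# Write VCF text lines to a temp file.
write_vcf_text <- function(body_lines, samples = c("S1", "S2", "S3"),
                           extra_header = character(0)) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    extra_header,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
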