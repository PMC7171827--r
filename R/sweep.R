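#' Sliding analysis windows over chromosomes
#'
#' Windows `[k * step, k * step + size)` (0-based half-open) per
#' chromosome, the final window truncated at the chromosome end;
#' generation stops once a window reaches the chromosome end, and
#' truncated tail windows shorter than `step` are discarded.  The
#' default 50 kb windows with 25 kb increments are the standard
#' sliding-window setting for genome scans.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp.
#' @param step Step between window starts in bp; must satisfy
#'   `0 < step <= size` (a larger step would leave uncovered gaps).
#' @return An object of class `window_set`: a data frame `windows`
#'   (chrom, start, end) plus the `size` and `step` used.
#' @export
make_windows <- function(chrom_lengths, size = 50000L, step = 25000L) {
  if (is.null(names(chrom_lengths)) || !length(chrom_lengths)) {
    stop("chrom_lengths must be a named vector")
  }
  stopifnot(size > 0, step > 0)
  if (step > size) stop("step must not exceed window size (gaps would drop sites)")
  out <- lapply(names(chrom_lengths), function(cc) {
    L <- chrom_lengths[[cc]]
    starts <- integer(0); ends <- integer(0)
    k <- 0
    repeat {
      s <- k * step
      if (s >= L) break
      e <- min(s + size, L)
      starts <- c(starts, s); ends <- c(ends, e)
      if (e >= L) break
      k <- k + 1
    }
    keep <- (ends - starts) >= step | (starts == 0 & ends == L)
    data.frame(chrom = cc, start = as.integer(starts[keep]),
               end = as.integer(ends[keep]), stringsAsFactors = FALSE)
  })
  structure(list(windows = do.call(rbind, out),
                 size = as.integer(size), step = as.integer(step)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows (size %d bp, step %d bp) on %d chromosome(s)\n",
              nrow(x$windows), x$size, x$step,
              length(unique(x$windows$chrom))))
  invisible(x)
}

## Overlap site positions (1-based) with windows (0-based half-open).
## Returns a hits object: queryHits = window row, subjectHits = site index.
.window_site_hits <- function(ws, chrom, pos) {
  w <- ws$windows
  gw <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
  gs <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::findOverlaps(gw, gs)
}

.new_window_stat <- function(ws, n_snps, value, stat_name) {
  out <- cbind(ws$windows, n_snps = n_snps, value = value)
  attr(out, "stat_name") <- stat_name
  class(out) <- c("window_stat", "data.frame")
  out
}

.check_aligned <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || !identical(a$start, b$start) ||
      !identical(a$end, b$end)) {
    stop("window series are not aligned (different window sets)")
  }
}

#' Per-site Weir-Cockerham variance components for two populations
#'
#' Computes the Weir & Cockerham (1984) variance components for each
#' site from the two populations' sample sizes, sample allele
#' frequencies and observed heterozygosity: `a` (among-population),
#' `b` (between individuals within populations) and `c` (within
#' individuals).  The per-site estimator is `theta = a / (a + b + c)`;
#' windowed estimates should combine sites as a ratio of sums
#' ([windowed_fst()]).  Sites with fewer than two non-missing genotypes
#' in either population are set to `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param pm A [pop_map()] covering all samples used.
#' @param popA,popB Population labels to contrast.
#' @return Data frame of class `site_fst` with columns chrom, pos, a, b,
#'   c; attribute `pops` records the pair.
#' @export
site_fst <- function(gm, pm, popA, popB) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(pm, "pop_map"))
  sA <- match(pop_samples(pm, popA), gm$samples)
  sB <- match(pop_samples(pm, popB), gm$samples)
  if (anyNA(sA) || anyNA(sB)) {
    stop("population samples missing from genotype matrix")
  }
  gA <- gm$geno[, sA, drop = FALSE]
  gB <- gm$geno[, sB, drop = FALSE]
  r <- 2                                 # number of populations
  n1 <- rowSums(!is.na(gA)); n2 <- rowSums(!is.na(gB))
  p1 <- rowSums(gA, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gB, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(gA == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(gB == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 < 2L | n2 < 2L
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  out <- data.frame(chrom = gm$chrom, pos = gm$pos, a = a, b = b, c = cc)
  attr(out, "pops") <- c(popA, popB)
  class(out) <- c("site_fst", "data.frame")
  out
}

#' Windowed Weir-Cockerham FST (ratio of averages)
#'
#' Per window, `sum(a) / sum(a + b + c)` over the informative sites it
#' contains; windows with fewer than `min_snps` informative sites (or a
#' non-positive denominator) are set missing.
#'
#' @param comp A `site_fst` component table from [site_fst()].
#' @param ws A `window_set` from [make_windows()].
#' @param min_snps Minimum informative sites per window.
#' @return A `window_stat` data frame (chrom, start, end, n_snps, value).
#' @export
windowed_fst <- function(comp, ws, min_snps = 10L) {
  stopifnot(inherits(comp, "site_fst"), inherits(ws, "window_set"))
  ok <- !is.na(comp$a)
  hits <- .window_site_hits(ws, comp$chrom, comp$pos)
  wi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  use <- ok[si]
  nw <- nrow(ws$windows)
  n_snps <- tabulate(wi[use], nbins = nw)
  num <- rep(0, nw); den <- rep(0, nw)
  if (any(use)) {
    agg_n <- tapply(comp$a[si[use]], wi[use], sum)
    tot <- comp$a + comp$b + comp$c
    agg_d <- tapply(tot[si[use]], wi[use], sum)
    ii <- as.integer(names(agg_n))
    num[ii] <- agg_n; den[ii] <- agg_d
  }
  value <- ifelse(n_snps >= min_snps & den > 0, num / den, NA_real_)
  pops <- attr(comp, "pops")
  .new_window_stat(ws, n_snps, value,
                   paste0("fst_", pops[1], "_", pops[2]))
}

#' Locus-specific branch length per window
#'
#' For focal population A, contrast B and outgroup C:
#' `LSBL(A; B, C) = (FST(AB) + FST(AC) - FST(BC)) / 2`, isolating the
#' differentiation accumulated on A's branch.  The analogous quantities
#' for the other two branches are obtained with `branch = "contrast"`
#' (B) or `"outgroup"` (C).  A window is missing if any input is
#' missing.  By construction `LSBL_A + LSBL_B = FST(AB)` per window.
#'
#' @param fst_ab,fst_ac,fst_bc Aligned `window_stat` series from
#'   [windowed_fst()] for the pairs (A,B), (A,C), (B,C).
#' @param branch Which branch length to return.
#' @return A `window_stat` data frame; `n_snps` is the minimum of the
#'   three inputs' per-window counts.
#' @export
lsbl <- function(fst_ab, fst_ac, fst_bc,
                 branch = c("focal", "contrast", "outgroup")) {
  branch <- match.arg(branch)
  .check_aligned(fst_ab, fst_ac)
  .check_aligned(fst_ab, fst_bc)
  v <- switch(branch,
              focal    = (fst_ab$value + fst_ac$value - fst_bc$value) / 2,
              contrast = (fst_ab$value + fst_bc$value - fst_ac$value) / 2,
              outgroup = (fst_ac$value + fst_bc$value - fst_ab$value) / 2)
  ws <- list(windows = fst_ab[, c("chrom", "start", "end")],
             size = NA_integer_, step = NA_integer_)
  .new_window_stat(ws, pmin(fst_ab$n_snps, fst_ac$n_snps, fst_bc$n_snps),
                   v, paste0("lsbl_", branch))
}

#' Windowed nucleotide diversity (pi) for one population
#'
#' Per site, `pi_site = 2 c_alt c_ref / (n_h (n_h - 1))` where the
#' allele counts are taken over the population's non-missing haplotypes
#' (`n_h` = twice the non-missing genotype count when unphased).  The
#' window value is the sum of per-site pi divided by the full window
#' length in bp (so monomorphic and absent positions contribute zero),
#' following the convention of per-window diversity in VCF-based scans.
#' Windows with fewer than `min_snps` informative sites are missing.
#'
#' @param gm A [genotype_matrix()].
#' @param pm A [pop_map()].
#' @param pop Population label.
#' @param ws A `window_set`.
#' @param min_snps Minimum informative sites per window.
#' @return A `window_stat` data frame (value = per-bp diversity).
#' @export
windowed_pi <- function(gm, pm, pop, ws, min_snps = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(ws, "window_set"))
  sp <- match(pop_samples(pm, pop), gm$samples)
  if (anyNA(sp)) stop("population samples missing from genotype matrix")
  g <- gm$geno[, sp, drop = FALSE]
  n_h <- 2 * rowSums(!is.na(g))
  c_alt <- rowSums(g, na.rm = TRUE)
  c_ref <- n_h - c_alt
  pi_site <- ifelse(n_h >= 2, 2 * c_alt * c_ref / (n_h * (n_h - 1)), NA_real_)
  ok <- !is.na(pi_site)
  hits <- .window_site_hits(ws, gm$chrom, gm$pos)
  wi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  use <- ok[si]
  nw <- nrow(ws$windows)
  n_snps <- tabulate(wi[use], nbins = nw)
  tot <- rep(0, nw)
  if (any(use)) {
    agg <- tapply(pi_site[si[use]], wi[use], sum)
    tot[as.integer(names(agg))] <- agg
  }
  len <- ws$windows$end - ws$windows$start
  value <- ifelse(n_snps >= min_snps, tot / len, NA_real_)
  .new_window_stat(ws, n_snps, value, paste0("pi_", pop))
}

#' Windowed pi-ratio (contrast over focal)
#'
#' `pi_contrast / pi_focal` per window; large values flag diversity loss
#' in the focal population.  Windows where the focal diversity falls
#' below `min_pi` (or either input is missing) are set missing rather
#' than infinite; the number of floored windows is reported via a
#' message.
#'
#' @param pi_contrast,pi_focal Aligned `window_stat` series from
#'   [windowed_pi()].
#' @param min_pi Floor on the focal (denominator) diversity.
#' @return A `window_stat` data frame.
#' @export
pi_ratio <- function(pi_contrast, pi_focal, min_pi = 1e-5) {
  .check_aligned(pi_contrast, pi_focal)
  floored <- !is.na(pi_focal$value) & pi_focal$value < min_pi
  if (any(floored)) {
    message("pi_ratio: ", sum(floored),
            " window(s) with focal pi below ", min_pi, " set missing")
  }
  v <- ifelse(is.na(pi_contrast$value) | is.na(pi_focal$value) | floored,
              NA_real_, pi_contrast$value / pi_focal$value)
  ws <- list(windows = pi_focal[, c("chrom", "start", "end")],
             size = NA_integer_, step = NA_integer_)
  .new_window_stat(ws, pmin(pi_contrast$n_snps, pi_focal$n_snps), v,
                   "pi_ratio")
}

#' Call empirical top-percentile outlier windows
#'
#' The threshold is the empirical `q`-quantile (linear interpolation) of
#' the non-missing window values; members are all windows with value at
#' or above the threshold, so ties at the threshold are included.
#'
#' @param stats A `window_stat` data frame.
#' @param q Quantile cutoff (default 0.99, the top 1 percent).
#' @return An object of class `outlier_set`: `stat_name`,
#'   `threshold`, `windows` (member rows of `stats`), `genes`
#'   (empty until [annotate_windows()]).
#' @export
call_outliers <- function(stats, q = 0.99) {
  stopifnot(inherits(stats, "window_stat"), q > 0, q < 1)
  vals <- stats$value[!is.na(stats$value)]
  if (!length(vals)) stop("all window values are missing")
  if (length(vals) < 100 / (1 - q)) {
    warning("only ", length(vals), " non-missing windows; the ",
            q, "-quantile threshold will be unstable")
  }
  thr <- stats::quantile(vals, q, names = FALSE, type = 7)
  if (max(vals) == min(vals)) {
    warning("all window values equal; every window ties at the threshold")
  }
  members <- !is.na(stats$value) & stats$value >= thr
  structure(list(stat_name = attr(stats, "stat_name"),
                 threshold = thr,
                 windows = stats[members, , drop = FALSE],
                 genes = character(0)),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set (%s): %d windows >= %.4g; %d gene(s)\n",
              x$stat_name, nrow(x$windows), x$threshold, length(x$genes)))
  invisible(x)
}

#' Annotate outlier windows with overlapping genes
#'
#' A gene is assigned if its interval overlaps any member window by at
#' least 1 bp; the gene list is deduplicated and sorted.
#'
#' @param outliers An `outlier_set` from [call_outliers()].
#' @param genes A `gene_annotation` (from [read_genes()] or
#'   [sim_gene_annotation()]).
#' @return The `outlier_set` with its `genes` field filled.
#' @export
annotate_windows <- function(outliers, genes) {
  stopifnot(inherits(outliers, "outlier_set"))
  w <- outliers$windows
  if (!nrow(w) || !nrow(genes)) {
    outliers$genes <- character(0)
    return(outliers)
  }
  gw <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hit <- GenomicRanges::findOverlaps(gg, gw)
  outliers$genes <- sort(unique(genes$gene_id[S4Vectors::queryHits(hit)]))
  outliers
}

#' Overlap of two candidate gene sets
#'
#' The headline candidate table: genes flagged by both selection tests,
#' plus each test's exclusive genes.
#'
#' @param psg_a,psg_b Character vectors of gene ids, or `outlier_set`
#'   objects (their `genes` field is used).
#' @return List with `shared`, `only_a`, `only_b` (sorted character
#'   vectors).
#' @export
overlap_genes <- function(psg_a, psg_b) {
  if (inherits(psg_a, "outlier_set")) psg_a <- psg_a$genes
  if (inherits(psg_b, "outlier_set")) psg_b <- psg_b$genes
  shared <- sort(intersect(psg_a, psg_b))
  if (!length(shared)) {
    message("overlap_genes: the two gene sets are disjoint")
  }
  list(shared = shared,
       only_a = sort(setdiff(psg_a, psg_b)),
       only_b = sort(setdiff(psg_b, psg_a)))
}

#' Manhattan-style plot of a windowed statistic
#'
#' One point per window at its midpoint, chromosomes laid side by side
#' with alternating shading, and an optional horizontal threshold line.
#'
#' @param stats A `window_stat` data frame.
#' @param threshold Optional horizontal cutoff to draw.
#' @param main Plot title (defaults to the statistic name).
#' @return Invisibly, `NULL`.
#' @export
plot_windows <- function(stats, threshold = NULL, main = NULL) {
  chroms <- unique(stats$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc)
    max(stats$end[stats$chrom == cc]), numeric(1))))
  names(offs) <- c(chroms, "_end")
  x <- (stats$start + stats$end) / 2 + offs[stats$chrom]
  col <- c("grey30", "steelblue")[1 + match(stats$chrom, chroms) %% 2]
  graphics::plot(x, stats$value, pch = 20, cex = 0.5, col = col,
                 xlab = "genome position (bp)",
                 ylab = attr(stats, "stat_name"),
                 main = if (is.null(main)) attr(stats, "stat_name") else main)
  if (!is.null(threshold)) {
    graphics::abline(h = threshold, lty = 2, col = "red")
  }
  invisible(NULL)
}
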