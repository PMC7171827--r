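#' Simulation configuration for three-population sweep data
#'
#' Defines a Balding-Nichols style neutral model with injected
#' focal-branch sweeps.  Each site draws an ancestral allele frequency
#' `p` from `Uniform(freq_range)`; each population then draws its own
#' frequency from a Beta distribution with mean `p` and variance
#' `p(1 - p) F`, where `F` is the population's drift parameter and plays
#' the role of the expected fixation index against the ancestor.  Inside
#' a sweep region the focal population uses the (larger) drift parameter
#' `F_sweep`, and its drawn frequency is then pushed deterministically
#' toward the nearer allele-frequency boundary so that its realized
#' heterozygosity `2q(1 - q)` is scaled by exactly `pi_scale`.  This
#' produces the two signals a sweep scan detects: elevated focal-branch
#' differentiation and reduced focal diversity.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (equal for all chromosomes).
#' @param n_snps_per_chrom SNP count per chromosome.
#' @param pops Data frame with columns `label`, `role` (one of `focal`,
#'   `contrast`, `outgroup`), `n` (diploid sample count) and `F` (drift
#'   parameter in (0, 1)).
#' @param sweeps Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, bp), `F_sweep` (drift in (0, 1), must exceed the focal
#'   `F`) and `pi_scale` (heterozygosity scaling factor in (0, 1]); may
#'   have zero rows for a fully neutral genome.
#' @param freq_range Length-2 numeric, the support of the uniform
#'   ancestral allele-frequency distribution.  The default (0.05, 0.95)
#'   avoids a preponderance of sites that are monomorphic in every
#'   sample; sites that still come out monomorphic are retained so the
#'   downstream site filter is exercised.
#' @param missing_rate Per-(site, sample) missing-genotype probability.
#' @param ts_prob Probability that a simulated substitution is a
#'   transition (A<->G or C<->T); the default 2.53/3.53 targets a
#'   transition/transversion ratio of 2.53, typical of chicken
#'   whole-genome SNP data.
#' @param gene_length,gene_gap Gene tiling for the toy annotation emitted
#'   by [write_simulation()]: fixed-length genes separated by gaps, so
#'   that window-to-gene annotation has both hits and misses.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the simulated dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L,
                       chrom_length = 1e6,
                       n_snps_per_chrom = 1000L,
                       pops = data.frame(
                         label = c("YFC", "NONYFC", "RJF"),
                         role = c("focal", "contrast", "outgroup"),
                         n = c(25L, 25L, 25L),
                         F = c(0.1, 0.1, 0.1)),
                       sweeps = data.frame(
                         chrom = character(), start = numeric(),
                         end = numeric(), F_sweep = numeric(),
                         pi_scale = numeric()),
                       freq_range = c(0.05, 0.95),
                       missing_rate = 0.01,
                       ts_prob = 2.53 / 3.53,
                       gene_length = 10000L,
                       gene_gap = 10000L,
                       seed = 1L) {
  stopifnot(is.data.frame(pops),
            all(c("label", "role", "n", "F") %in% names(pops)))
  if (any(pops$F <= 0 | pops$F >= 1)) {
    stop("population drift parameter F must lie strictly in (0, 1)")
  }
  if (any(pops$n < 1)) stop("each population needs at least one sample")
  if (anyDuplicated(pops$label)) stop("duplicate population labels")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  stopifnot(n_chrom >= 1, chrom_length > 0, n_snps_per_chrom >= 1,
            length(freq_range) == 2, freq_range[1] < freq_range[2],
            freq_range[1] > 0, freq_range[2] < 1,
            ts_prob > 0, ts_prob < 1)
  chroms <- paste0("chr", seq_len(n_chrom))
  if (nrow(sweeps)) {
    stopifnot(all(c("chrom", "start", "end", "F_sweep", "pi_scale")
                  %in% names(sweeps)))
    if (!all(sweeps$chrom %in% chroms)) {
      stop("sweep region on unknown chromosome")
    }
    if (any(sweeps$start < 0 | sweeps$end > chrom_length |
            sweeps$start >= sweeps$end)) {
      stop("sweep regions must lie within chromosome bounds")
    }
    if (any(sweeps$F_sweep <= 0 | sweeps$F_sweep >= 1)) {
      stop("F_sweep must lie strictly in (0, 1)")
    }
    f_focal <- pops$F[pops$role == "focal"]
    if (length(f_focal) && any(sweeps$F_sweep <= f_focal)) {
      stop("F_sweep must exceed the focal population's F")
    }
    if (any(sweeps$pi_scale <= 0 | sweeps$pi_scale > 1)) {
      stop("pi_scale must lie in (0, 1]")
    }
  }
  structure(
    list(n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
         n_snps_per_chrom = as.integer(n_snps_per_chrom), pops = pops,
         sweeps = sweeps, freq_range = freq_range,
         missing_rate = missing_rate, ts_prob = ts_prob,
         gene_length = as.integer(gene_length),
         gene_gap = as.integer(gene_gap), seed = as.integer(seed),
         chroms = chroms),
    class = "sim_config"
  )
}

## Rescale a frequency q so that heterozygosity 2q(1-q) is multiplied by
## s, moving q toward its nearer boundary (0 or 1); exact for s in (0,1].
.scale_het <- function(q, s) {
  disc <- pmax(0, 1 - 4 * s * q * (1 - q))
  ifelse(q <= 0.5, (1 - sqrt(disc)) / 2, (1 + sqrt(disc)) / 2)
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' Samples site positions, alleles, ancestral frequencies and one realized
#' frequency per population per site.  Population frequencies follow
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, i.e. mean `p` and variance
#' `p (1 - p) F`.  Sites inside a sweep region use `F_sweep` for the focal
#' population and then have the focal frequency pushed toward the nearer
#' boundary so the focal heterozygosity is scaled by `pi_scale`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_freqs`: per-site `chrom`, `pos`,
#'   `ref`, `alt`, `in_sweep` flag, and a sites x populations `freq`
#'   matrix (columns named by population label).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per <- config$n_snps_per_chrom
  chrom <- rep(config$chroms, each = n_per)
  pos <- as.integer(unlist(lapply(config$chroms, function(cc) {
    sort(sample.int(config$chrom_length, n_per))
  })))
  n <- length(pos)

  ## alleles: pick ref uniformly, then a transition partner with ts_prob
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  is_ts <- stats::runif(n) < config$ts_prob
  alt <- character(n)
  alt[is_ts] <- ts_partner[ref[is_ts]]
  tv_pick <- function(r) {
    cand <- setdiff(bases, c(r, ts_partner[[r]]))
    cand[sample.int(2L, 1L)]
  }
  alt[!is_ts] <- vapply(ref[!is_ts], tv_pick, character(1))

  p_anc <- stats::runif(n, config$freq_range[1], config$freq_range[2])
  in_sweep <- rep(FALSE, n)
  sw <- config$sweeps
  if (nrow(sw)) {
    for (k in seq_len(nrow(sw))) {
      in_sweep <- in_sweep |
        (chrom == sw$chrom[k] & pos > sw$start[k] & pos <= sw$end[k])
    }
  }
  focal_lab <- config$pops$label[config$pops$role == "focal"]
  freq <- matrix(NA_real_, n, nrow(config$pops),
                 dimnames = list(NULL, config$pops$label))
  for (i in seq_len(nrow(config$pops))) {
    F <- rep(config$pops$F[i], n)
    lab <- config$pops$label[i]
    if (length(focal_lab) && lab == focal_lab && nrow(sw)) {
      for (k in seq_len(nrow(sw))) {
        idx <- chrom == sw$chrom[k] & pos > sw$start[k] & pos <= sw$end[k]
        F[idx] <- sw$F_sweep[k]
      }
    }
    q <- stats::rbeta(n, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    if (length(focal_lab) && lab == focal_lab && nrow(sw)) {
      for (k in seq_len(nrow(sw))) {
        idx <- chrom == sw$chrom[k] & pos > sw$start[k] & pos <= sw$end[k]
        q[idx] <- .scale_het(q[idx], sw$pi_scale[k])
      }
    }
    freq[, i] <- q
  }
  structure(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt,
         p_anc = p_anc, in_sweep = in_sweep, freq = freq, config = config),
    class = "sim_freqs"
  )
}

#' Sample diploid genotypes and phased haplotypes from realized frequencies
#'
#' Each individual's two haplotype alleles are independent Bernoulli draws
#' at its population's site frequency; the genotype dosage is their sum.
#' Missingness is applied independently per (site, sample) at
#' `missing_rate`, blanking the genotype and both haplotypes.
#'
#' @param freqs A `sim_freqs` object from [simulate_frequencies()].
#' @return A list with components `gm` (a [genotype_matrix()] with phased
#'   haplotypes) and `popmap` (a [pop_map()]).
#' @export
simulate_genotypes <- function(freqs) {
  stopifnot(inherits(freqs, "sim_freqs"))
  config <- freqs$config
  set.seed(config$seed + 1L)
  n <- length(freqs$pos)
  pops <- config$pops
  total_n <- sum(pops$n)
  haplo <- matrix(NA_integer_, n, 2L * total_n)
  samples <- character(total_n)
  assign <- character(total_n)
  col0 <- 0L
  for (i in seq_len(nrow(pops))) {
    ni <- pops$n[i]
    h <- matrix(stats::rbinom(n * 2L * ni, 1L, rep(freqs$freq[, i], 2L * ni)),
                nrow = n)
    haplo[, col0 * 2L + seq_len(2L * ni)] <- h
    idx <- col0 + seq_len(ni)
    samples[idx] <- sprintf("%s_%02d", pops$label[i], seq_len(ni))
    assign[idx] <- pops$label[i]
    col0 <- col0 + ni
  }
  geno <- haplo[, seq(1L, 2L * total_n, by = 2L), drop = FALSE] +
    haplo[, seq(2L, 2L * total_n, by = 2L), drop = FALSE]
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * total_n) < config$missing_rate,
                   n, total_n)
    geno[miss] <- NA_integer_
    haplo[, seq(1L, 2L * total_n, by = 2L)][miss] <- NA_integer_
    haplo[, seq(2L, 2L * total_n, by = 2L)][miss] <- NA_integer_
  }
  lens <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                          config$chroms)
  gm <- genotype_matrix(freqs$chrom, freqs$pos, freqs$ref, freqs$alt,
                        geno, samples, haplo = haplo, chrom_lengths = lens)
  pm <- pop_map(stats::setNames(assign, samples),
                stats::setNames(pops$role, pops$label))
  list(gm = gm, popmap = pm)
}

#' Toy gene annotation tiled across the simulated genome
#'
#' Fixed-length genes separated by fixed gaps on every chromosome, named
#' `<chrom>_g<k>`.
#'
#' @param config A [sim_config()].
#' @return A `gene_annotation` data frame (chrom, start, end, gene_id)
#'   with 0-based half-open intervals.
#' @export
sim_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pitch <- config$gene_length + config$gene_gap
  out <- do.call(rbind, lapply(config$chroms, function(cc) {
    starts <- seq(0L, config$chrom_length - config$gene_length, by = pitch)
    data.frame(chrom = cc, start = starts,
               end = starts + config$gene_length,
               gene_id = sprintf("%s_g%03d", cc, seq_along(starts)),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Assemble the ground truth of a simulated dataset
#'
#' @param freqs A `sim_freqs` object.
#' @param genes A `gene_annotation` (defaults to [sim_gene_annotation()]
#'   of the same config).
#' @return A list of class `sim_truth`: `regions` (the sweep regions),
#'   `genes` (gene ids overlapping any sweep region), and the realized
#'   per-population frequency table.
#' @export
sim_truth <- function(freqs, genes = sim_gene_annotation(freqs$config)) {
  stopifnot(inherits(freqs, "sim_freqs"))
  reg <- freqs$config$sweeps
  gids <- character(0)
  if (nrow(reg)) {
    gr_reg <- GenomicRanges::GRanges(
      reg$chrom, IRanges::IRanges(reg$start + 1L, reg$end))
    gr_gen <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    hit <- GenomicRanges::findOverlaps(gr_gen, gr_reg)
    gids <- sort(unique(genes$gene_id[S4Vectors::queryHits(hit)]))
  }
  structure(list(regions = reg[, c("chrom", "start", "end")],
                 genes = gids, freq = freqs$freq,
                 sites = data.frame(chrom = freqs$chrom, pos = freqs$pos,
                                    in_sweep = freqs$in_sweep)),
            class = "sim_truth")
}

#' Simulate a complete dataset in one call
#'
#' Convenience wrapper: frequencies, genotypes, toy gene annotation and
#' truth, fully determined by the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return List with `gm`, `popmap`, `genes`, `truth`, `freqs`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  freqs <- simulate_frequencies(config)
  gt <- simulate_genotypes(freqs)
  genes <- sim_gene_annotation(config)
  truth <- sim_truth(freqs, genes)
  list(gm = gt$gm, popmap = gt$popmap, genes = genes, truth = truth,
       freqs = freqs, config = config)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits a phased VCF v4.2 (`sim.vcf`), a population map TSV
#' (`popmap.tsv`: sample, population, role), a BED4 gene annotation
#' (`genes.bed`), a truth table of sweep regions (`truth_regions.tsv`),
#' the sweep gene ids (`truth_genes.tsv`) and the realized
#' per-population allele frequencies (`truth_freqs.tsv`).  The VCF body
#' round-trips losslessly through [read_vcf()].
#'
#' @param sim A list from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(outdir, "sim.vcf"),
             popmap = file.path(outdir, "popmap.tsv"),
             genes = file.path(outdir, "genes.bed"),
             truth_regions = file.path(outdir, "truth_regions.tsv"),
             truth_genes = file.path(outdir, "truth_genes.tsv"),
             truth_freqs = file.path(outdir, "truth_freqs.tsv"))
  write_vcf(sim$gm, paths[["vcf"]])
  pm <- sim$popmap
  utils::write.table(
    data.frame(sample = names(pm$assignments),
               population = unname(pm$assignments),
               role = unname(pm$roles[pm$assignments])),
    paths[["popmap"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$genes[, c("chrom", "start", "end", "gene_id")],
                     paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$regions, paths[["truth_regions"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$genes, paths[["truth_genes"]])
  utils::write.table(
    cbind(data.frame(chrom = sim$freqs$chrom, pos = sim$freqs$pos),
          as.data.frame(sim$freqs$freq)),
    paths[["truth_freqs"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Truth sweep windows of a simulation under a given window set
#'
#' The analysis windows (from [make_windows()]) that are fully contained
#' in a sweep region; these are the windows a scan is expected to flag.
#'
#' @param truth A `sim_truth` (or any data frame of regions with columns
#'   chrom, start, end).
#' @param ws A `window_set` from [make_windows()].
#' @return Data frame of windows (chrom, start, end).
#' @export
truth_sweep_windows <- function(truth, ws) {
  reg <- if (inherits(truth, "sim_truth")) truth$regions else truth
  w <- ws$windows
  keep <- rep(FALSE, nrow(w))
  for (k in seq_len(nrow(reg))) {
    keep <- keep | (w$chrom == reg$chrom[k] & w$start >= reg$start[k] &
                      w$end <= reg$end[k])
  }
  w[keep, c("chrom", "start", "end"), drop = FALSE]
}
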