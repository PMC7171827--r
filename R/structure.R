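#' Greedy windowed LD pruning of SNP sites
#'
#' PLINK-style `--indep-pairwise` pruning: within each sliding window of
#' `window_snps` consecutive sites (advancing by `step_snps`, per
#' chromosome), site pairs with squared genotype correlation above
#' `r2_max` are resolved by dropping the later (higher-index) site.
#' Missing genotypes are pairwise-excluded from the correlation; a
#' zero-variance site has r-squared 0 against every partner and thus
#' cannot be pruned for LD.  Defaults follow the common
#' `--indep-pairwise 50 10 0.1` setting.
#'
#' @param gm A [genotype_matrix()].
#' @param window_snps Window width in SNPs.
#' @param step_snps Step between window starts in SNPs.
#' @param r2_max Maximum tolerated squared correlation.
#' @return Sorted integer vector of retained site indices into `gm`.
#' @export
ld_prune <- function(gm, window_snps = 50L, step_snps = 10L, r2_max = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"),
            window_snps >= 2L, step_snps >= 1L, r2_max >= 0)
  keep <- rep(TRUE, n_sites(gm))
  for (cc in unique(gm$chrom)) {
    idx <- which(gm$chrom == cc)
    if (length(idx) < 2L) next
    for (w0 in seq(1L, length(idx), by = step_snps)) {
      w <- idx[w0:min(w0 + window_snps - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2L) next
      cm <- suppressWarnings(
        stats::cor(t(gm$geno[w, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r2 <- cm^2
      r2[is.na(r2)] <- 0
      act <- rep(TRUE, length(w))
      for (j in 2:length(w)) {
        prev <- which(act[seq_len(j - 1L)])
        if (length(prev) && any(r2[prev, j] > r2_max)) act[j] <- FALSE
      }
      keep[w[!act]] <- FALSE
    }
  }
  which(keep)
}

#' Principal component analysis of a genotype matrix
#'
#' GCTA-style standardization: missing genotypes are mean-imputed per
#' site, each site is centered by `2 p` and scaled by
#' `sqrt(2 p (1 - p))` where `p` is the sample alternative-allele
#' frequency; sites with zero variance (or fixed `p`) are excluded.  The
#' top components of the resulting sample covariance decomposition are
#' returned, with each component's sign fixed so its largest-magnitude
#' sample coordinate is positive.
#'
#' @param gm A [genotype_matrix()] with at least 2 samples.
#' @param n_components Number of leading components to return.
#' @return An object of class `gm_pca`: `coords` (samples x components,
#'   rownames = sample ids), `explained` (variance fractions per
#'   returned component, summing to at most 1), `n_sites_used`.
#' @export
pca_genotypes <- function(gm, n_components = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) < 2L) stop("PCA needs at least 2 samples")
  G <- t(gm$geno)  # samples x sites
  mu <- colMeans(G, na.rm = TRUE)
  nai <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nai)) G[nai] <- mu[nai[, 2L]]
  p <- mu / 2
  v <- apply(G, 2L, stats::var)
  use <- which(p > 0 & p < 1 & v > 0 & !is.na(v))
  if (n_components > min(nrow(G), length(use))) {
    stop("n_components exceeds min(samples, usable sites) = ",
         min(nrow(G), length(use)))
  }
  X <- sweep(G[, use, drop = FALSE], 2L, 2 * p[use], "-")
  X <- sweep(X, 2L, sqrt(2 * p[use] * (1 - p[use])), "/")
  sv <- svd(X, nu = n_components, nv = 0L)
  d <- sv$d
  coords <- sv$u %*% diag(d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(gm$samples,
                           paste0("PC", seq_len(n_components)))
  structure(list(coords = coords,
                 explained = d[seq_len(n_components)]^2 / sum(d^2),
                 n_sites_used = length(use)),
            class = "gm_pca")
}

## 1 - IBS distance on a raw dosage matrix (sites x samples).
## IBS(i, j) = mean over shared non-missing sites of (2 - |g_i - g_j|)/2.
.ibs_distance <- function(geno, samples) {
  m0 <- (!is.na(geno) & geno == 0L) * 1
  m1 <- (!is.na(geno) & geno == 1L) * 1
  m2 <- (!is.na(geno) & geno == 2L) * 1
  mm <- m0 + m1 + m2  # non-missing indicator
  n_shared <- crossprod(mm)
  s02 <- crossprod(m0, m2)
  s1x <- crossprod(m1, m0 + m2)
  diffsum <- 2 * (s02 + t(s02)) + s1x + t(s1x)
  if (any(n_shared == 0)) {
    bad <- which(n_shared == 0, arr.ind = TRUE)[1L, ]
    stop("sample pair with no shared non-missing sites: ",
         samples[bad[1L]], " / ", samples[bad[2L]])
  }
  d <- diffsum / (2 * n_shared)
  diag(d) <- 0
  dimnames(d) <- list(samples, samples)
  d
}

#' Pairwise 1 - IBS distance matrix between samples
#'
#' Identity-by-state similarity between two samples is the mean over
#' shared non-missing sites of `(2 - |g_i - g_j|) / 2`; the distance is
#' its complement.  Errors (naming the pair) if two samples share no
#' non-missing site.
#'
#' @param gm A [genotype_matrix()].
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
pairwise_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  .ibs_distance(gm$geno, gm$samples)
}

#' Neighbor-joining tree rooted to an outgroup
#'
#' Builds the Saitou-Nei neighbor-joining tree from a distance matrix
#' and roots it at the midpoint of the outgroup's pendant edge.  The NJ
#' agglomeration itself is delegated to [ape::nj()]; negative branch
#' length estimates are retained in the object and clamped to zero only
#' at serialization ([write_newick()]).
#'
#' @param dm Symmetric distance matrix with dimnames (e.g. from
#'   [pairwise_distance()]).
#' @param root_label Label of the outgroup leaf to root on.
#' @return An [ape::phylo] object (rooted).
#' @export
nj_tree <- function(dm, root_label) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 labels")
  labs <- rownames(dm)
  if (is.null(labs)) stop("distance matrix must carry labels")
  if (!root_label %in% labs) stop("root label not in distance matrix: ",
                                  root_label)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix not symmetric")
  tr <- ape::nj(dm)
  tr <- ape::root(tr, outgroup = root_label, resolve.root = TRUE)
  rn <- ape::Ntip(tr) + 1L
  re <- which(tr$edge[, 1L] == rn)
  tip_i <- which(tr$tip.label == root_label)
  tipedge <- re[tr$edge[re, 2L] == tip_i]
  otheredge <- setdiff(re, tipedge)
  if (length(tipedge) == 1L && length(otheredge) == 1L) {
    tot <- sum(tr$edge.length[c(tipedge, otheredge)])
    tr$edge.length[tipedge] <- tot / 2
    tr$edge.length[otheredge] <- tot / 2
  }
  tr
}

#' Site-bootstrap support for the NJ tree
#'
#' Resamples sites with replacement, rebuilds the 1 - IBS distance and
#' the rooted NJ tree per replicate, and scores each internal edge of
#' the reference tree by the percentage of replicates whose tree
#' contains the same bipartition.  Supports are stored in the returned
#' tree's `node.label`.
#'
#' @param gm A [genotype_matrix()].
#' @param root_label Outgroup leaf for rooting.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed for the site resampling.
#' @return The rooted reference NJ tree with `node.label` support values
#'   in `[0, 100]` (root node blank).
#' @export
bootstrap_support <- function(gm, root_label, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"), n_reps >= 1L)
  ref <- nj_tree(pairwise_distance(gm), root_label)
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    si <- sample.int(n_sites(gm), replace = TRUE)
    d <- .ibs_distance(gm$geno[si, , drop = FALSE], gm$samples)
    boots[[b]] <- nj_tree(d, root_label)
  }
  cnt <- ape::prop.clades(ref, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  supp <- round(100 * cnt / n_reps)
  supp[1L] <- NA  # root node: support undefined
  ref$node.label <- ifelse(is.na(supp), "", as.character(supp))
  ref
}

#' Serialize a tree to Newick, clamping negative branch lengths
#'
#' Negative NJ branch-length estimates are set to zero at serialization
#' (a common display convention; the topology is untouched).
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  tree$edge.length <- pmax(tree$edge.length, 0)
  ape::write.tree(tree, file = path)
  invisible(path)
}
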