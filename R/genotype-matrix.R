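#' Construct a genotype matrix
#'
#' The central data container of the package: a sites-by-samples table of
#' diploid genotype dosages (0, 1, 2 copies of the alternative allele, `NA`
#' for missing) together with per-site metadata (chromosome, 1-based
#' position, reference and alternative allele) and, optionally, phased
#' haplotypes as a sites-by-(2 x samples) 0/1 matrix.
#'
#' Sites are stored sorted by chromosome (order of first appearance) and
#' position; duplicate (chromosome, position) pairs are rejected.  When
#' phased haplotypes are supplied, their per-sample allele sums must agree
#' with the genotype dosages wherever both are non-missing.
#'
#' @param chrom Character vector of chromosome identifiers, one per site.
#' @param pos Integer vector of 1-based positions, one per site.
#' @param ref,alt Single-base reference/alternative alleles per site.
#' @param geno Integer matrix, sites x samples, values in \{0, 1, 2, NA\}.
#' @param samples Character vector of sample identifiers (columns of `geno`).
#' @param haplo Optional integer matrix, sites x (2 x samples), values in
#'   \{0, 1, NA\}; columns `2i - 1` and `2i` are the two haplotypes of
#'   sample `i`.
#' @param chrom_lengths Optional named integer vector of chromosome lengths
#'   (used downstream to build windows); names must cover `chrom`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, samples,
                            haplo = NULL, chrom_lengths = NULL) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  geno <- as.matrix(geno)
  if (nrow(geno) != n) {
    stop("geno must have one row per site")
  }
  if (ncol(geno) != length(samples)) {
    stop("geno must have one column per sample")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- as.character(chrom)[ord]
  pos <- as.integer(pos)[ord]
  ref <- as.character(ref)[ord]
  alt <- as.character(alt)[ord]
  geno <- geno[ord, , drop = FALSE]
  if (anyDuplicated(paste(chrom, pos))) {
    stop("duplicate (chrom, pos) sites are not allowed")
  }
  if (!is.null(haplo)) {
    haplo <- as.matrix(haplo)[ord, , drop = FALSE]
    if (ncol(haplo) != 2L * length(samples)) {
      stop("haplo must have two columns per sample")
    }
    hsum <- haplo[, seq(1L, ncol(haplo), by = 2L), drop = FALSE] +
      haplo[, seq(2L, ncol(haplo), by = 2L), drop = FALSE]
    both <- !is.na(hsum) & !is.na(geno)
    if (any(hsum[both] != geno[both])) {
      stop("phased haplotype allele sums disagree with genotypes")
    }
  }
  colnames(geno) <- samples
  structure(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt,
         geno = geno, haplo = haplo, samples = as.character(samples),
         chrom_lengths = chrom_lengths),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d chromosome%s)%s\n",
              n_sites(x), n_samples(x), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s",
              if (is.null(x$haplo)) "" else ", phased"))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(gm) length(gm$chrom)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site index and/or sample
#'
#' @param gm A `genotype_matrix`.
#' @param sites Integer index vector of sites to keep (in order).
#' @param samples Character vector of sample ids or integer index.
#' @return A `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  if (is.null(samples)) {
    scol <- seq_len(n_samples(gm))
  } else if (is.character(samples)) {
    scol <- match(samples, gm$samples)
    if (anyNA(scol)) {
      stop("unknown sample(s): ", paste(samples[is.na(scol)], collapse = ", "))
    }
  } else {
    scol <- samples
  }
  hap <- NULL
  if (!is.null(gm$haplo)) {
    hcol <- as.vector(rbind(2L * scol - 1L, 2L * scol))
    hap <- gm$haplo[sites, hcol, drop = FALSE]
  }
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites], gm$geno[sites, scol, drop = FALSE],
                  gm$samples[scol], haplo = hap,
                  chrom_lengths = gm$chrom_lengths)
}

#' Construct a population map
#'
#' Maps every sample to a population label and assigns each population a
#' role for branch statistics: `focal` (the population scanned for
#' sweeps), `contrast` (the phenotypic contrast group), `outgroup` (the
#' rooting population), or `none`.
#'
#' @param assignments Named character vector: `sample id -> population`.
#' @param roles Named character vector: `population -> role`; populations
#'   not listed default to role `none`.
#' @return An object of class `pop_map`.
#' @export
pop_map <- function(assignments, roles = NULL) {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be uniquely named by sample id")
  }
  pops <- unique(unname(assignments))
  r <- stats::setNames(rep("none", length(pops)), pops)
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), pops)
    if (length(unknown)) {
      stop("role assigned to unknown population(s): ",
           paste(unknown, collapse = ", "))
    }
    ok <- c("focal", "contrast", "outgroup", "none")
    if (!all(roles %in% ok)) {
      stop("roles must be one of: ", paste(ok, collapse = ", "))
    }
    r[names(roles)] <- roles
  }
  for (role in c("focal", "outgroup")) {
    if (sum(r == role) > 1L) stop("more than one ", role, " population")
  }
  structure(list(assignments = assignments, roles = r), class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  tab <- table(x$assignments)
  cat("pop_map:\n")
  for (p in names(tab)) {
    cat(sprintf("  %s: %d samples (role: %s)\n", p, tab[[p]], x$roles[[p]]))
  }
  invisible(x)
}

#' Samples belonging to a population
#' @param pm A `pop_map`.
#' @param pop Population label.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(pm, pop) {
  if (!pop %in% unname(pm$assignments)) {
    stop("unknown population label: ", pop)
  }
  names(pm$assignments)[pm$assignments == pop]
}

#' Population holding a given role
#' @param pm A `pop_map`.
#' @param role One of `"focal"`, `"contrast"`, `"outgroup"`.
#' @return Population label (length-1 character).
#' @export
role_population <- function(pm, role) {
  hit <- names(pm$roles)[pm$roles == role]
  if (length(hit) != 1L) {
    stop("expected exactly one population with role '", role, "', found ",
         length(hit))
  }
  hit
}

#' Check that every sample of a genotype matrix is mapped
#'
#' @param gm A `genotype_matrix`.
#' @param pm A `pop_map`.
#' @return Invisibly `TRUE`; errors naming the first unmapped sample.
#' @export
check_popmap <- function(gm, pm) {
  missing <- setdiff(gm$samples, names(pm$assignments))
  if (length(missing)) {
    stop("sample(s) in genotype matrix absent from population map: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
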