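#' Write a genotype matrix as VCF v4.2
#'
#' Emits phased `a|b` GT fields when the matrix carries haplotypes,
#' unphased `a/b` otherwise; missing genotypes become `.|.` / `./.`.
#' Chromosome lengths, when known, are recorded as `##contig` header
#' lines so windows can be rebuilt from the file alone.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan"), con)
  if (!is.null(gm$chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(gm$chrom_lengths),
                       as.integer(gm$chrom_lengths)), con)
  }
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  n <- n_sites(gm)
  if (is.null(gm$haplo)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = n)
    gt[is.na(gm$geno)] <- "./."
  } else {
    a1 <- gm$haplo[, seq(1L, ncol(gm$haplo), 2L), drop = FALSE]
    a2 <- gm$haplo[, seq(2L, ncol(gm$haplo), 2L), drop = FALSE]
    gt <- matrix(paste(ifelse(is.na(a1), ".", a1),
                       ifelse(is.na(a2), ".", a2), sep = "|"), nrow = n)
  }
  body <- cbind(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

## "chr:start-end" (1-based inclusive) or list(chrom, start, end) -> list
.parse_region <- function(region) {
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4L) {
      stop("region must look like 'chr:start-end', got: ", region)
    }
    region <- list(chrom = m[2],
                   start = as.numeric(gsub(",", "", m[3])),
                   end = as.numeric(gsub(",", "", m[4])))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(region)),
            region$start <= region$end)
  region
}

#' Read a VCF into a genotype matrix
#'
#' Retains only biallelic single-nucleotide records; multi-allelic and
#' non-SNP records are skipped and counted (attribute `n_skipped`,
#' reported via a message).  GT fields are parsed into dosages; any GT
#' containing `.` (including half-missing calls like `./1`) is treated
#' as missing.  When every retained GT uses the `|` phase separator the
#' phased haplotype slot is filled; mixed phasing leaves it empty.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region Optional `"chr:start-end"` string (1-based inclusive)
#'   or list with `chrom`, `start`, `end`; only overlapping sites are
#'   returned.  A region containing no sites yields an empty matrix.
#' @return A [genotype_matrix()]; attribute `n_skipped` holds the count
#'   of skipped non-SNP/multi-allelic records.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  is_snp <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " non-SNP or multi-allelic record(s)")
  }
  keep <- which(is_snp)
  if (!is.null(region)) {
    region <- .parse_region(region)
    keep <- keep[chrom[keep] == region$chrom & pos[keep] >= region$start &
                   pos[keep] <= region$end]
  }
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1L]
  gt <- gt_raw[keep, -1L, drop = FALSE]
  ## strip any extra FORMAT fields beyond GT
  gt[] <- sub(":.*$", "", gt)
  n <- length(keep)
  if (n == 0L) {
    return(genotype_matrix(character(0), integer(0), character(0),
                           character(0),
                           matrix(integer(0), 0, length(samples)), samples))
  }
  known <- c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1")
  dosage <- c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L)
  code <- match(gt, known)
  bad <- is.na(code) & !grepl(".", gt, fixed = TRUE) & !is.na(gt)
  if (any(bad)) {
    stop("unparseable GT field(s), e.g.: ", gt[which(bad)[1]])
  }
  geno <- matrix(dosage[code], n, length(samples))
  phased <- all(grepl("|", gt[!is.na(gt) & !grepl(".", gt, fixed = TRUE)],
                      fixed = TRUE)) &&
    !any(grepl("/", gt, fixed = TRUE))
  haplo <- NULL
  if (phased && length(samples)) {
    a1 <- suppressWarnings(matrix(as.integer(substr(gt, 1L, 1L)),
                                  n, length(samples)))
    a2 <- suppressWarnings(matrix(as.integer(substr(gt, 3L, 3L)),
                                  n, length(samples)))
    haplo <- matrix(NA_integer_, n, 2L * length(samples))
    haplo[, seq(1L, 2L * length(samples), 2L)] <- a1
    haplo[, seq(2L, 2L * length(samples), 2L)] <- a2
  }
  lens <- NULL
  meta <- v@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", ctg)
    ln <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", ctg)))
    if (!anyNA(ln)) lens <- stats::setNames(ln, ids)
  }
  gm <- genotype_matrix(chrom[keep], pos[keep], ref[keep], alt[keep],
                        geno, samples, haplo = haplo, chrom_lengths = lens)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Screen sites on missingness and minor-allele count
#'
#' Retains sites whose missing-genotype fraction is at most
#' `max_missing` and whose minor-allele count across all samples is at
#' least `min_mac`.  Idempotent; preserves site order.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction per site.
#' @param min_mac Minimum minor-allele count (`min_mac = 1` drops sites
#'   monomorphic in the sample).
#' @return A filtered [genotype_matrix()].
#' @export
filter_sites <- function(gm, max_missing = 0.2, min_mac = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- n_samples(gm)
  n_miss <- rowSums(is.na(gm$geno))
  alt_c <- rowSums(gm$geno, na.rm = TRUE)
  tot_c <- 2L * (ns - n_miss)
  mac <- pmin(alt_c, tot_c - alt_c)
  keep <- which(n_miss / ns <= max_missing & mac >= min_mac)
  subset_gm(gm, sites = keep)
}

#' Per-dataset variant summary
#'
#' Classifies each site's substitution as a transition (A<->G, C<->T) or
#' transversion and counts heterozygous and homozygous-alternative
#' genotypes per sample.  The Ts/Tv ratio is `NA` when there are no
#' transversions.
#'
#' @param gm A [genotype_matrix()] of biallelic SNPs.
#' @return An object of class `variant_summary`: `n_sites`,
#'   `n_transitions`, `n_transversions`, `tstv_ratio`,
#'   `per_sample_het`, `per_sample_hom_alt` (named integer vectors).
#' @export
variant_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  bases <- c("A", "C", "G", "T")
  if (n_sites(gm) && !all(gm$ref %in% bases & gm$alt %in% bases)) {
    stop("variant_summary requires single-base SNP alleles")
  }
  pair <- paste0(pmin(gm$ref, gm$alt), pmax(gm$ref, gm$alt))
  is_ts <- pair %in% c("AG", "CT")
  n_ts <- sum(is_ts)
  n_tv <- sum(!is_ts)
  het <- colSums(gm$geno == 1L, na.rm = TRUE)
  hom <- colSums(gm$geno == 2L, na.rm = TRUE)
  structure(
    list(n_sites = n_sites(gm), n_transitions = n_ts,
         n_transversions = n_tv,
         tstv_ratio = if (n_tv > 0) n_ts / n_tv else NA_real_,
         per_sample_het = het, per_sample_hom_alt = hom),
    class = "variant_summary"
  )
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf(
    "variant_summary: %d SNPs; Ts = %d, Tv = %d, Ts/Tv = %s\n",
    x$n_sites, x$n_transitions, x$n_transversions,
    ifelse(is.na(x$tstv_ratio), "NA", sprintf("%.3f", x$tstv_ratio))))
  cat(sprintf("mean per-sample het = %.1f, hom-alt = %.1f\n",
              mean(x$per_sample_het), mean(x$per_sample_hom_alt)))
  invisible(x)
}

#' Read a sample-to-population map from TSV
#'
#' Expects two or three tab-separated columns without header: sample id,
#' population label and (optionally) the population's role (`focal`,
#' `contrast`, `outgroup` or `none`).
#'
#' @param path TSV file path.
#' @return A [pop_map()].
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("popmap needs at least sample and population")
  if (anyDuplicated(tab[[1L]])) {
    stop("duplicate sample row(s) in popmap: ",
         paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
  }
  roles <- NULL
  if (ncol(tab) >= 3L) {
    rr <- tapply(tab[[3L]], tab[[2L]], function(z) unique(z))
    if (any(lengths(rr) > 1L)) {
      stop("conflicting roles within a population in popmap")
    }
    roles <- stats::setNames(unlist(rr), names(rr))
  }
  pop_map(stats::setNames(tab[[2L]], tab[[1L]]), roles)
}

#' Read a BED4 gene annotation
#'
#' @param path BED file (0-based half-open, columns chrom, start, end,
#'   name).
#' @return A `gene_annotation` data frame with columns `chrom`, `start`,
#'   `end`, `gene_id`; empty input yields an empty annotation.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L ||
      !length(readLines(path, n = 1L, warn = FALSE))) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0))
    class(out) <- c("gene_annotation", "data.frame")
    return(out)
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stop("every BED interval needs a non-empty gene id in column 4")
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    gene_id = nm, stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED interval with start >= end")
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Concatenate genotype matrices over disjoint site sets
#'
#' Utility for combining per-chromosome matrices with identical samples.
#'
#' @param ... `genotype_matrix` objects with identical sample vectors.
#' @return A [genotype_matrix()].
#' @export
concat_gm <- function(...) {
  gms <- list(...)
  stopifnot(length(gms) >= 1L)
  samples <- gms[[1L]]$samples
  for (g in gms) stopifnot(identical(g$samples, samples))
  hap <- NULL
  if (all(vapply(gms, function(g) !is.null(g$haplo), logical(1)))) {
    hap <- do.call(rbind, lapply(gms, `[[`, "haplo"))
  }
  genotype_matrix(
    unlist(lapply(gms, `[[`, "chrom")),
    unlist(lapply(gms, `[[`, "pos")),
    unlist(lapply(gms, `[[`, "ref")),
    unlist(lapply(gms, `[[`, "alt")),
    do.call(rbind, lapply(gms, `[[`, "geno")),
    samples, haplo = hap)
}
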