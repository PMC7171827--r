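#' Extract a population-ordered haplotype matrix over a region
#'
#' Builds the haplotypes-by-sites matrix used for region heatmaps, cells
#' coded 0 = reference allele, 1 = alternative allele, `NA` = missing.
#' With phased input every sample contributes two rows (its two phase
#' columns).  Unphased input falls back to one genotype-coded row per
#' sample: 0 for homozygous reference, 1 for homozygous alternative and
#' `NA` for heterozygous or missing calls — the honest representation
#' when no phasing is available; no imputation is ever performed.  Rows
#' are grouped into population blocks in `pop_order`, samples sorted by
#' id within each block.
#'
#' @param gm A [genotype_matrix()].
#' @param pm A [pop_map()] covering all samples.
#' @param region `"chr:start-end"` string (1-based inclusive) or list
#'   with `chrom`, `start`, `end`.
#' @param pop_order Character vector giving the display order of the
#'   population blocks; defaults to the populations in map order.  Must
#'   cover every population present in the matrix.
#' @return An object of class `haplotype_matrix`: `mat` (rows x sites),
#'   `row_ids`, `blocks` (data frame pop/from/to, 1-based row ranges),
#'   `chrom`, `pos`, `ref`, `alt`, `phased` flag.
#' @export
extract_haplotypes <- function(gm, pm, region, pop_order = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(pm, "pop_map"))
  check_popmap(gm, pm)
  region <- .parse_region(region)
  sites <- which(gm$chrom == region$chrom & gm$pos >= region$start &
                   gm$pos <= region$end)
  if (!length(sites)) stop("region contains no sites")
  pops_present <- unique(unname(pm$assignments[gm$samples]))
  if (is.null(pop_order)) pop_order <- pops_present
  unknown <- setdiff(pop_order, pops_present)
  if (length(unknown)) {
    stop("unknown population(s) in pop_order: ",
         paste(unknown, collapse = ", "))
  }
  uncovered <- setdiff(pops_present, pop_order)
  if (length(uncovered)) {
    stop("pop_order must cover all populations; missing: ",
         paste(uncovered, collapse = ", "))
  }
  phased <- !is.null(gm$haplo)
  rows <- list(); ids <- character(0); blocks <- NULL
  for (p in pop_order) {
    sm <- sort(intersect(pop_samples(pm, p), gm$samples))
    from <- length(ids) + 1L
    if (phased) {
      for (s in sm) {
        i <- match(s, gm$samples)
        rows[[length(rows) + 1L]] <- gm$haplo[sites, 2L * i - 1L]
        rows[[length(rows) + 1L]] <- gm$haplo[sites, 2L * i]
        ids <- c(ids, paste0(s, "_h1"), paste0(s, "_h2"))
      }
    } else {
      for (s in sm) {
        g <- gm$geno[sites, match(s, gm$samples)]
        rows[[length(rows) + 1L]] <-
          ifelse(is.na(g) | g == 1L, NA_integer_, ifelse(g == 0L, 0L, 1L))
        ids <- c(ids, s)
      }
    }
    blocks <- rbind(blocks, data.frame(pop = p, from = from,
                                       to = length(ids),
                                       stringsAsFactors = FALSE))
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  colnames(mat) <- paste0(region$chrom, ":", gm$pos[sites])
  structure(list(mat = mat, row_ids = ids, blocks = blocks,
                 chrom = region$chrom, pos = gm$pos[sites],
                 ref = gm$ref[sites], alt = gm$alt[sites],
                 phased = phased),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "haplotype_matrix: %d %s x %d sites on %s (%d population blocks)\n",
    nrow(x$mat), if (x$phased) "haplotypes" else "genotype-coded samples",
    ncol(x$mat), x$chrom, nrow(x$blocks)))
  invisible(x)
}

#' Export a haplotype matrix as TSV (and optional heatmap)
#'
#' The TSV has one row per haplotype with columns `row_id`,
#' `population`, then one column per site (named `chrom:pos`) holding
#' 0/1/NA.  The optional PNG heatmap uses grey for reference alleles,
#' indian red for alternative alleles and white for missing cells, with
#' white gap rows separating population blocks.
#'
#' @param hm A `haplotype_matrix` from [extract_haplotypes()].
#' @param path Output TSV path.
#' @param png_path Optional output PNG path for the heatmap.
#' @return Invisibly, `path`.
#' @export
export_haplotype_matrix <- function(hm, path, png_path = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  pop_of_row <- character(nrow(hm$mat))
  for (k in seq_len(nrow(hm$blocks))) {
    pop_of_row[hm$blocks$from[k]:hm$blocks$to[k]] <- hm$blocks$pop[k]
  }
  tab <- data.frame(row_id = hm$row_ids, population = pop_of_row,
                    hm$mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(png_path)) {
    plot_haplotype_matrix(hm, png_path)
  }
  invisible(path)
}

#' Render a haplotype heatmap to PNG
#'
#' @param hm A `haplotype_matrix`.
#' @param png_path Output PNG path.
#' @param gap Number of blank rows drawn between population blocks.
#' @return Invisibly, `png_path`.
#' @export
plot_haplotype_matrix <- function(hm, png_path, gap = 2L) {
  nb <- nrow(hm$blocks)
  n_rows <- nrow(hm$mat) + gap * (nb - 1L)
  disp <- matrix(NA_real_, n_rows, ncol(hm$mat))
  at <- numeric(nb)
  r0 <- 0L
  for (k in seq_len(nb)) {
    idx <- hm$blocks$from[k]:hm$blocks$to[k]
    disp[r0 + seq_along(idx), ] <- hm$mat[idx, ]
    at[k] <- r0 + length(idx) / 2
    r0 <- r0 + length(idx) + gap
  }
  grDevices::png(png_path, width = 1000, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 6, 2, 1))
  ## image() draws row 1 at the bottom; flip so block order reads top-down
  graphics::image(x = seq_len(ncol(disp)), y = seq_len(n_rows),
                  z = t(disp[n_rows:1, , drop = FALSE]),
                  col = c("grey70", "indianred"), zlim = c(0, 1),
                  xlab = sprintf("site index (%s:%d-%d)", hm$chrom,
                                 min(hm$pos), max(hm$pos)),
                  ylab = "", yaxt = "n", useRaster = TRUE)
  graphics::axis(2, at = n_rows - at + 1, labels = hm$blocks$pop,
                 las = 1, tick = FALSE)
  invisible(png_path)
}

#' Re-read an exported haplotype matrix TSV
#'
#' Inverse of [export_haplotype_matrix()] (up to the `phased` flag,
#' which is inferred from the row ids).
#'
#' @param path TSV path written by [export_haplotype_matrix()].
#' @return A `haplotype_matrix`.
#' @export
read_haplotype_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab$row_id
  sitelab <- colnames(mat)
  chrom <- sub(":.*$", "", sitelab[1])
  pos <- as.integer(sub("^.*:", "", sitelab))
  rle_pop <- rle(tab$population)
  to <- cumsum(rle_pop$lengths)
  blocks <- data.frame(pop = rle_pop$values,
                       from = c(1L, utils::head(to, -1L) + 1L), to = to,
                       stringsAsFactors = FALSE)
  structure(list(mat = mat, row_ids = tab$row_id, blocks = blocks,
                 chrom = chrom, pos = pos,
                 ref = rep(NA_character_, length(pos)),
                 alt = rep(NA_character_, length(pos)),
                 phased = any(grepl("_h[12]$", tab$row_id))),
            class = "haplotype_matrix")
}
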