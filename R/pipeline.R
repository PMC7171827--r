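#' Pipeline configuration
#'
#' Validated bag of paths and parameters for [run_all()].  Defaults are
#' the standard scan settings: 50 kb windows with 25 kb increments, top
#' 1 percent outliers, LD pruning at (50, 10, 0.1) and 100 bootstrap
#' replicates for the NJ tree.
#'
#' @param vcf,popmap,genes Input file paths (VCF, popmap TSV, BED4).
#' @param outdir Output directory.
#' @param window_size,window_step Window geometry in bp.
#' @param q Outlier quantile.
#' @param min_snps Minimum informative SNPs per window.
#' @param min_pi Focal-diversity floor for the pi-ratio denominator.
#' @param max_missing,min_mac Site-filter settings ([filter_sites()]).
#' @param prune Length-3 numeric: LD-pruning window (SNPs), step (SNPs)
#'   and maximum r-squared.
#' @param n_pcs Number of principal components to report.
#' @param boot NJ bootstrap replicates (0 disables the bootstrap).
#' @param region Optional `"chr:start-end"` region for the haplotype
#'   stage; `NULL` skips that stage.
#' @param pop_order Optional population display order for the haplotype
#'   matrix.
#' @param clip_negative_fst If `TRUE`, clip negative per-window FST
#'   values to zero in the written tables (display only; LSBL always
#'   uses unclipped values so its additivity identity holds).
#' @param seed Integer seed driving the bootstrap resampling.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, popmap, genes, outdir,
                            window_size = 50000L, window_step = 25000L,
                            q = 0.99, min_snps = 10L, min_pi = 1e-5,
                            max_missing = 0.2, min_mac = 1L,
                            prune = c(50L, 10L, 0.1),
                            n_pcs = 10L, boot = 100L,
                            region = NULL, pop_order = NULL,
                            clip_negative_fst = FALSE, seed = 1L) {
  stopifnot(q > 0, q < 1, min_snps >= 0, min_pi >= 0, length(prune) == 3L,
            n_pcs >= 1L, boot >= 0L)
  if (window_step > window_size) {
    stop("step must not exceed window size (gaps would drop sites)")
  }
  structure(list(vcf = vcf, popmap = popmap, genes = genes,
                 outdir = outdir, window_size = as.integer(window_size),
                 window_step = as.integer(window_step), q = q,
                 min_snps = as.integer(min_snps), min_pi = min_pi,
                 max_missing = max_missing, min_mac = as.integer(min_mac),
                 prune = prune, n_pcs = as.integer(n_pcs),
                 boot = as.integer(boot), region = region,
                 pop_order = pop_order,
                 clip_negative_fst = isTRUE(clip_negative_fst),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  message("[", name, "] ", appendLF = FALSE)
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("done (%.1fs)", as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full pipeline
#'
#' Executes, in order: variant summary, site filtering, population
#' structure (LD pruning, PCA, 1 - IBS distances, rooted NJ tree with
#' bootstrap support), the sweep scan (windowed FST for the three
#' population pairs, focal LSBL, windowed pi for focal and contrast,
#' pi-ratio, top-percentile outliers, gene annotation and the two-test
#' overlap) and, when a region is configured, the haplotype-matrix
#' stage.  All results are written as TSV/Newick/PNG files under
#' `config$outdir` together with a `manifest.yaml` recording the package
#' version, configuration and seed.  Any stage failure aborts with a
#' stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the main result objects.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$vcf, config$popmap, config$genes)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$outdir, ...)

  gm <- .stage("read", read_vcf(config$vcf))
  pm <- read_popmap(config$popmap)
  check_popmap(gm, pm)
  genes <- read_genes(config$genes)

  summ <- .stage("summarize", variant_summary(gm))
  .write_tsv(data.frame(n_sites = summ$n_sites,
                        n_transitions = summ$n_transitions,
                        n_transversions = summ$n_transversions,
                        tstv_ratio = summ$tstv_ratio),
             od("variant_summary.tsv"))
  .write_tsv(data.frame(sample = gm$samples,
                        het = summ$per_sample_het,
                        hom_alt = summ$per_sample_hom_alt),
             od("per_sample_counts.tsv"))

  gmf <- .stage("filter", filter_sites(gm, config$max_missing,
                                       config$min_mac))

  res_structure <- .stage("structure", {
    pruned <- ld_prune(gmf, config$prune[1], config$prune[2],
                       config$prune[3])
    writeLines(sprintf("%s\t%d", gmf$chrom[pruned], gmf$pos[pruned]),
               od("pruned_sites.tsv"))
    gmp <- subset_gm(gmf, sites = pruned)
    pca <- pca_genotypes(gmp, min(config$n_pcs, n_samples(gmp) - 1L,
                                  n_sites(gmp)))
    .write_tsv(data.frame(sample = rownames(pca$coords),
                          population = unname(pm$assignments[rownames(pca$coords)]),
                          pca$coords, check.names = FALSE),
               od("pca_coords.tsv"))
    .write_tsv(data.frame(component = colnames(pca$coords),
                          explained = pca$explained),
               od("pca_explained.tsv"))
    root_pop <- role_population(pm, "outgroup")
    root_sample <- sort(pop_samples(pm, root_pop))[1L]
    tree <- if (config$boot > 0L) {
      bootstrap_support(gmf, root_sample, n_reps = config$boot,
                        seed = config$seed)
    } else {
      nj_tree(pairwise_distance(gmf), root_sample)
    }
    write_newick(tree, od("nj_tree.nwk"))
    list(pruned = pruned, pca = pca, tree = tree)
  })

  res_scan <- .stage("scan", {
    lens <- gm$chrom_lengths
    if (is.null(lens)) {
      lens <- tapply(gmf$pos, gmf$chrom, max)
      lens <- stats::setNames(as.numeric(lens), names(lens))
    }
    ws <- make_windows(lens, config$window_size, config$window_step)
    A <- role_population(pm, "focal")
    B <- role_population(pm, "contrast")
    C <- role_population(pm, "outgroup")
    fab <- windowed_fst(site_fst(gmf, pm, A, B), ws, config$min_snps)
    fac <- windowed_fst(site_fst(gmf, pm, A, C), ws, config$min_snps)
    fbc <- windowed_fst(site_fst(gmf, pm, B, C), ws, config$min_snps)
    lb <- lsbl(fab, fac, fbc, branch = "focal")
    pif <- windowed_pi(gmf, pm, A, ws, config$min_snps)
    pic <- windowed_pi(gmf, pm, B, ws, config$min_snps)
    pr <- pi_ratio(pic, pif, config$min_pi)
    for (st in list(fab, fac, fbc)) {
      out <- st
      if (config$clip_negative_fst) out$value <- pmax(out$value, 0)
      .write_tsv(out, od(paste0(attr(st, "stat_name"), ".tsv")))
    }
    .write_tsv(lb, od("lsbl.tsv"))
    .write_tsv(pif, od(paste0("pi_", A, ".tsv")))
    .write_tsv(pic, od(paste0("pi_", B, ".tsv")))
    .write_tsv(pr, od("pi_ratio.tsv"))
    out_l <- annotate_windows(call_outliers(lb, config$q), genes)
    out_p <- annotate_windows(call_outliers(pr, config$q), genes)
    .write_tsv(out_l$windows, od("outliers_lsbl.tsv"))
    .write_tsv(out_p$windows, od("outliers_pi_ratio.tsv"))
    ov <- overlap_genes(out_l, out_p)
    .write_tsv(data.frame(
      gene_id = c(ov$shared, ov$only_a, ov$only_b),
      set = rep(c("both", "lsbl_only", "pi_ratio_only"),
                c(length(ov$shared), length(ov$only_a),
                  length(ov$only_b)))),
      od("candidate_genes.tsv"))
    for (st in list(lb, pr)) {
      thr <- if (identical(attr(st, "stat_name"), "lsbl_focal"))
        out_l$threshold else out_p$threshold
      grDevices::png(od(paste0(attr(st, "stat_name"), "_manhattan.png")),
                     width = 1200, height = 400)
      plot_windows(st, threshold = thr)
      grDevices::dev.off()
    }
    list(windows = ws, fst = list(AB = fab, AC = fac, BC = fbc),
         lsbl = lb, pi_focal = pif, pi_contrast = pic, pi_ratio = pr,
         outliers_lsbl = out_l, outliers_pi_ratio = out_p, overlap = ov)
  })

  res_haplo <- NULL
  if (!is.null(config$region)) {
    res_haplo <- .stage("haplo", {
      hm <- extract_haplotypes(gm, pm, config$region, config$pop_order)
      export_haplotype_matrix(hm, od("haplotypes.tsv"),
                              od("haplotype_heatmap.png"))
      hm
    })
  }

  yaml::write_yaml(
    list(package = "sweepscan",
         version = as.character(utils::packageVersion("sweepscan")),
         seed = config$seed,
         config = lapply(unclass(config), function(x)
           if (is.null(x)) NULL else unname(x))),
    od("manifest.yaml"))

  invisible(list(summary = summ, structure = res_structure,
                 scan = res_scan, haplo = res_haplo,
                 gm = gm, popmap = pm, genes = genes))
}

#' Demonstration configuration: simulated three-population sweep study
#'
#' The standing demo dataset: 15 chromosomes of 1 Mb at 2.5 SNP/kb
#' (the order of magnitude seen in whole-genome chicken resequencing),
#' three populations (focal, contrast, outgroup; 25 diploid samples
#' each) at neutral drift F = 0.1, and three 75 kb focal-branch sweep
#' regions (F_sweep = 0.6, pi_scale = 0.1) aligned to the toy gene
#' tiling so every truth gene lies inside a sweep region.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
demo_sim_config <- function(seed = 1L) {
  sim_config(
    n_chrom = 15L, chrom_length = 1e6, n_snps_per_chrom = 2500L,
    sweeps = data.frame(
      chrom = c("chr1", "chr2", "chr3"),
      start = c(400000, 300000, 600000),
      end = c(475000, 375000, 675000),
      F_sweep = 0.6, pi_scale = 0.1),
    seed = seed)
}

#' One-shot end-to-end demo on simulated data
#'
#' Simulates the [demo_sim_config()] dataset, writes it to
#' `outdir/input`, runs the full pipeline into `outdir/results`, and
#' evaluates the scan against the simulation truth: the fraction of
#' truth sweep windows (windows fully inside a sweep region) recovered
#' in the top percentile of each statistic, and whether every truth
#' sweep gene appears in the two-test gene intersection.
#'
#' @param outdir Output directory.
#' @param seed Integer seed (drives both the simulation and the
#'   pipeline's bootstrap).
#' @param boot NJ bootstrap replicates for the structure stage.
#' @return Invisibly, a list: `pipeline` ([run_all()] results), `truth`,
#'   `truth_windows`, `recall_lsbl`, `recall_pi_ratio`,
#'   `truth_genes_in_overlap`.
#' @export
run_demo <- function(outdir = tempfile("sweepscan_demo"), seed = 1L,
                     boot = 100L) {
  sim <- simulate_dataset(demo_sim_config(seed))
  paths <- write_simulation(sim, file.path(outdir, "input"))
  config <- pipeline_config(
    vcf = paths[["vcf"]], popmap = paths[["popmap"]],
    genes = paths[["genes"]], outdir = file.path(outdir, "results"),
    region = "chr1:400001-475000",
    pop_order = sim$config$pops$label, boot = boot, seed = seed)
  res <- run_all(config)
  tw <- truth_sweep_windows(sim$truth, res$scan$windows)
  wkey <- function(w) paste(w$chrom, w$start, w$end)
  in_top <- function(out) mean(wkey(tw) %in% wkey(out$windows))
  recall_l <- in_top(res$scan$outliers_lsbl)
  recall_p <- in_top(res$scan$outliers_pi_ratio)
  genes_ok <- all(sim$truth$genes %in% res$scan$overlap$shared)
  message(sprintf(
    "demo: truth-window recall LSBL %.2f, pi-ratio %.2f; truth genes in overlap: %s",
    recall_l, recall_p, genes_ok))
  invisible(list(pipeline = res, truth = sim$truth, truth_windows = tw,
                 recall_lsbl = recall_l, recall_pi_ratio = recall_p,
                 truth_genes_in_overlap = genes_ok,
                 config = config, sim = sim))
}
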