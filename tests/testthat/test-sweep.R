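test_that("window bookkeeping matches the sliding-window contract", {
  ws <- make_windows(c(chr1 = 100000), size = 50000, step = 25000)
  expect_equal(ws$windows$start, c(0L, 25000L, 50000L))
  expect_equal(ws$windows$end, c(50000L, 75000L, 100000L))

  # chromosome shorter than one window: single truncated window
  ws2 <- make_windows(c(chr1 = 40000))
  expect_equal(nrow(ws2$windows), 1L)
  expect_equal(ws2$windows$end, 40000L)

  # count formula floor((L - size)/step) + 1 on an exact fit
  ws3 <- make_windows(c(chr1 = 1e6))
  expect_equal(nrow(ws3$windows), 39L)
  expect_true(all(diff(ws3$windows$start) == 25000L))

  expect_error(make_windows(c(chr1 = 1e6), size = 1000, step = 2000),
               "step")
})

test_that("Weir-Cockerham components match a longhand transcription", {
  pm <- pop_map(setNames(c(rep("A", 10), rep("B", 10)),
                         paste0("S", 1:20)),
                c(A = "focal", B = "contrast"))

  # worked table: A = 6 x 0/0 + 4 x 0/1 ; B = 2 x 0/0 + 8 x 1/1
  gA <- c(rep(0L, 6), rep(1L, 4))
  gB <- c(rep(0L, 2), rep(2L, 8))
  gm <- make_gm(matrix(c(gA, gB), nrow = 1))
  comp <- site_fst(gm, pm, "A", "B")
  expect_equal(unlist(comp[1, c("a", "b", "c")]),
               wc_oracle(gA, gB), tolerance = 1e-12, ignore_attr = TRUE)

  # fixed difference: theta = 1
  gmf <- make_gm(matrix(c(rep(0L, 10), rep(2L, 10)), nrow = 1))
  cf <- site_fst(gmf, pm, "A", "B")
  expect_equal(cf$a / (cf$a + cf$b + cf$c), 1)

  # identical populations: no differentiation, a <= 0
  gmi <- make_gm(matrix(rep(c(0L, 1L, 2L, 1L, 0L), 4), nrow = 1))
  ci <- site_fst(gmi, pm, "A", "B")
  expect_lte(ci$a, 0)
  expect_lte(ci$a / (ci$a + ci$b + ci$c), 0)

  expect_error(site_fst(gm, pm, "A", "Z"), "unknown population")

  # randomized tables against the oracle, with missing data
  set.seed(77)
  for (rep in 1:25) {
    g <- sample(c(0:2, NA), 20, replace = TRUE,
                prob = c(0.3, 0.3, 0.3, 0.1))
    gmr <- make_gm(matrix(g, nrow = 1))
    cr <- site_fst(gmr, pm, "A", "B")
    or <- wc_oracle(g[1:10], g[11:20])
    expect_equal(unlist(cr[1, c("a", "b", "c")]), or,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("windowed FST is the ratio of summed components", {
  pm <- pop_map(setNames(c(rep("A", 5), rep("B", 5)), paste0("S", 1:10)),
                c(A = "focal", B = "contrast"))
  set.seed(13)
  g <- matrix(sample(0:2, 3 * 10, replace = TRUE), nrow = 3)
  gm <- make_gm(g, pos = c(100L, 200L, 300L))
  comp <- site_fst(gm, pm, "A", "B")
  ws <- make_windows(c(chr1 = 1000), size = 1000, step = 1000)
  wf <- windowed_fst(comp, ws, min_snps = 1L)
  num <- 0; den <- 0
  for (i in 1:3) {
    o <- wc_oracle(g[i, 1:5], g[i, 6:10])
    num <- num + o[["a"]]
    den <- den + sum(o)
  }
  expect_equal(wf$value, num / den, tolerance = 1e-12)
  expect_equal(wf$n_snps, 3L)

  # a single-site window equals that site's theta
  ws1 <- make_windows(c(chr1 = 150), size = 150, step = 150)
  w1 <- windowed_fst(comp, ws1, min_snps = 1L)
  o1 <- wc_oracle(g[1, 1:5], g[1, 6:10])
  expect_equal(w1$value, o1[["a"]] / sum(o1), tolerance = 1e-12)

  # all-fixed-difference window: value 1
  gmx <- make_gm(matrix(rep(c(rep(0L, 5), rep(2L, 5)), each = 1,
                            times = 3), nrow = 3, byrow = TRUE),
                 pos = c(10L, 20L, 30L))
  wx <- windowed_fst(site_fst(gmx, pm, "A", "B"), ws1, min_snps = 1L)
  expect_equal(wx$value, 1)

  # windows below min_snps are missing
  wmin <- windowed_fst(comp, ws, min_snps = 5L)
  expect_true(is.na(wmin$value))
})

test_that("LSBL follows the branch-length formula and its identity", {
  f_ab <- make_stat(0.5, stat_name = "fst_A_B")
  f_ac <- make_stat(0.3, stat_name = "fst_A_C")
  f_bc <- make_stat(0.2, stat_name = "fst_B_C")
  expect_equal(lsbl(f_ab, f_ac, f_bc, "focal")$value, 0.3)

  # all three equal x -> x/2
  x <- make_stat(0.4)
  expect_equal(lsbl(x, x, x, "focal")$value, 0.2)

  # additivity LSBL_A + LSBL_B = FST(AB), with missing propagation
  set.seed(3)
  ab <- make_stat(runif(50)); ac <- make_stat(runif(50))
  bc <- make_stat(runif(50))
  ab$value[7] <- NA
  la <- lsbl(ab, ac, bc, "focal")
  lb <- lsbl(ab, ac, bc, "contrast")
  expect_equal(la$value + lb$value, ab$value, tolerance = 1e-15)
  expect_true(is.na(la$value[7]))

  misaligned <- make_stat(runif(49))
  expect_error(lsbl(ab, ac, misaligned), "not aligned")
})

test_that("per-site pi equals the enumerated mean pairwise difference", {
  pm <- pop_map(setNames(rep("P", 3), paste0("S", 1:3)), c(P = "focal"))
  # 4 haplotypes with allele counts 2/2 -> pi = 2/3
  gm <- make_gm(matrix(c(2L, 0L, 1L), nrow = 1), samples = paste0("S", 1:3))
  ws <- make_windows(c(chr1 = 10), size = 10, step = 10)
  # restrict to the two homozygous samples: counts 2 alt / 2 ref
  gm2 <- subset_gm(gm, samples = c("S1", "S2"))
  pm2 <- pop_map(setNames(rep("P", 2), c("S1", "S2")), c(P = "focal"))
  p <- windowed_pi(gm2, pm2, "P", ws, min_snps = 1L)
  expect_equal(p$value * 10, 2 * 2 * 2 / (4 * 3))
  expect_equal(p$value * 10, pi_enum(c(1, 1, 0, 0)))

  # random tables with up to 6 haplotypes vs pair enumeration
  set.seed(29)
  for (rep in 1:30) {
    nh <- sample(c(4L, 6L), 1L)
    haps <- sample(0:1, nh, replace = TRUE)
    g <- haps[seq(1, nh, 2)] + haps[seq(2, nh, 2)]
    # force genotype-derived counts to match the haplotypes (no het order info)
    gmr <- make_gm(matrix(as.integer(g), nrow = 1),
                   samples = paste0("S", seq_len(nh / 2)))
    pmr <- pop_map(setNames(rep("P", nh / 2), gmr$samples), c(P = "focal"))
    pr <- windowed_pi(gmr, pmr, "P", ws, min_snps = 1L)
    expect_equal(pr$value * 10, pi_enum(haps), tolerance = 1e-12)
  }

  # two haplotypes differing at 3 of 1000 bp: pi = 0.003
  pm1 <- pop_map(setNames("P", "S1"), c(P = "focal"))
  gm1 <- make_gm(matrix(rep(1L, 3), ncol = 1), pos = c(100L, 500L, 900L),
                 samples = "S1")
  ws1k <- make_windows(c(chr1 = 1000), size = 1000, step = 1000)
  p1 <- windowed_pi(gm1, pm1, "P", ws1k, min_snps = 1L)
  expect_equal(p1$value, 0.003)

  # monomorphic window: 0
  gm0 <- make_gm(matrix(c(0L, 0L), nrow = 1), samples = c("S1", "S2"))
  p0 <- windowed_pi(gm0, pop_map(setNames(rep("P", 2), c("S1", "S2"))),
                    "P", ws, min_snps = 1L)
  expect_equal(p0$value, 0)
})

test_that("pi is an unbiased estimator of 2p(1-p)", {
  set.seed(61)
  p <- 0.3
  for (nh in c(4L, 20L, 200L)) {
    n_sites_mc <- 4000L
    haps <- matrix(rbinom(n_sites_mc * nh, 1L, p), ncol = nh)
    calt <- rowSums(haps)
    pi_site <- 2 * calt * (nh - calt) / (nh * (nh - 1))
    expect_equal(mean(pi_site), 2 * p * (1 - p), tolerance = 0.03)
  }
})

test_that("pi-ratio guards its denominator", {
  num <- make_stat(c(0.004, 0.002, 0.003))
  den <- make_stat(c(0.001, 1e-6, NA))
  expect_message(pr <- pi_ratio(num, den, min_pi = 1e-5), "1 window")
  expect_equal(pr$value, c(4, NA, NA))
  expect_error(pi_ratio(num, make_stat(1:2)), "not aligned")
})

test_that("windowed FST recovers the simulated drift parameter", {
  for (F in c(0.05, 0.2)) {
    cfg <- sim_config(n_chrom = 3L, chrom_length = 1e6,
                      n_snps_per_chrom = 1200L,
                      pops = data.frame(label = c("A", "B", "C"),
                                        role = c("focal", "contrast",
                                                 "outgroup"),
                                        n = 25L, F = F),
                      seed = 101L)
    sim <- simulate_dataset(cfg)
    ws <- make_windows(sim$gm$chrom_lengths)
    f <- windowed_fst(site_fst(sim$gm, sim$popmap, "A", "B"), ws)
    expect_lt(abs(mean(f$value, na.rm = TRUE) - F), 0.03)
  }
})

test_that("neutral pi-ratio centers at one", {
  cfg <- sim_config(n_chrom = 3L, chrom_length = 1e6,
                    n_snps_per_chrom = 1200L, seed = 71L)
  sim <- simulate_dataset(cfg)
  ws <- make_windows(sim$gm$chrom_lengths)
  pf <- windowed_pi(sim$gm, sim$popmap, "YFC", ws)
  pc <- windowed_pi(sim$gm, sim$popmap, "NONYFC", ws)
  pr <- pi_ratio(pc, pf)
  med <- median(pr$value, na.rm = TRUE)
  expect_gt(med, 0.8)
  expect_lt(med, 1.25)
})

test_that("outlier calling reproduces a sort-based quantile oracle", {
  # 1000 distinct values at q = 0.99: exactly the top 10
  st <- make_stat(sample(seq(0.001, 1, length.out = 1000)))
  out <- suppressWarnings(call_outliers(st, q = 0.99))
  expect_equal(nrow(out$windows), 10L)
  expect_setequal(out$windows$value, sort(st$value, decreasing = TRUE)[1:10])

  # threshold equals the independent interpolation oracle
  set.seed(19)
  vals <- rnorm(200)
  st2 <- make_stat(vals)
  out2 <- suppressWarnings(call_outliers(st2, q = 0.99))
  thr <- quantile_oracle(vals, 0.99)
  expect_equal(out2$threshold, thr, tolerance = 1e-12)
  expect_setequal(out2$windows$value, vals[vals >= thr])

  # degenerate: all equal -> everything ties at the threshold
  suppressWarnings(
    expect_warning(outd <- call_outliers(make_stat(rep(1, 150))),
                   "ties|equal"))
  expect_equal(nrow(outd$windows), 150L)

  allna <- make_stat(c(NA_real_, NA_real_))
  expect_error(suppressWarnings(call_outliers(allna)), "missing")
})

test_that("gene annotation is 1-bp overlap against the outlier windows", {
  st <- make_stat(c(1, 2, 10))  # windows [0,1000) [1000,2000) [2000,3000)
  out <- suppressWarnings(call_outliers(st, q = 0.6))
  expect_equal(out$windows$start, 2000L)
  genes <- data.frame(
    chrom = "chr1",
    start = c(0L, 1999L, 2999L, 3000L, 2500L),
    end = c(100L, 2001L, 3000L, 3500L, 2600L),
    gene_id = c("gA", "gB", "gC", "gD", "gE"))
  class(genes) <- c("gene_annotation", "data.frame")
  ann <- annotate_windows(out, genes)
  expect_equal(ann$genes, c("gB", "gC", "gE"))

  # brute-force all-pairs overlap oracle on a toy layout
  st2 <- make_stat(c(5, 1, 7, 2, 9))
  out2 <- suppressWarnings(call_outliers(st2, q = 0.5))
  ann2 <- annotate_windows(out2, genes)
  expected <- character(0)
  for (g in seq_len(nrow(genes))) for (w in seq_len(nrow(out2$windows))) {
    if (genes$start[g] < out2$windows$end[w] &&
        genes$end[g] > out2$windows$start[w]) {
      expected <- c(expected, genes$gene_id[g])
    }
  }
  expect_equal(ann2$genes, sort(unique(expected)))
})

test_that("two-test gene overlap splits shared and exclusive sets", {
  ov <- overlap_genes(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$shared, c("b", "c"))
  expect_equal(ov$only_a, "a")
  expect_equal(ov$only_b, "d")
  expect_message(overlap_genes(c("a"), c("b")), "disjoint")
})
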