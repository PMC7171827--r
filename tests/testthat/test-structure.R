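test_that("LD pruning drops later members of correlated pairs", {
  base <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L),
                c(2L, 0L, 1L, 1L, 0L, 2L, 1L, 0L))
  # three identical copies of site 1: only the first survives
  gm <- make_gm(rbind(base[1, ], base[1, ], base[1, ], base[2, ]))
  kept <- ld_prune(gm, window_snps = 10L, step_snps = 2L, r2_max = 0.1)
  expect_equal(kept, c(1L, 4L))

  # mutually independent sites are all retained
  set.seed(5)
  indep <- matrix(sample(0:2, 5 * 60, replace = TRUE), nrow = 5)
  gmi <- make_gm(indep)
  kepti <- ld_prune(gmi, window_snps = 10L, step_snps = 2L, r2_max = 0.99)
  expect_equal(kepti, 1:5)

  # zero-variance site cannot be pruned for LD
  gmz <- make_gm(rbind(base[1, ], rep(1L, 8), base[1, ]))
  expect_true(2L %in% ld_prune(gmz, 10L, 2L, 0.1))
})

test_that("LD pruning matches the all-pairs oracle on toy matrices", {
  set.seed(17)
  for (rep in 1:5) {
    g <- matrix(sample(0:2, 8 * 30, replace = TRUE), nrow = 8)
    g[3, ] <- g[1, ]                 # duplicated column pair
    g[sample(length(g), 10)] <- NA
    gm <- make_gm(g)
    kept <- ld_prune(gm, window_snps = 20L, step_snps = 5L, r2_max = 0.1)
    expect_equal(kept, prune_oracle(g, 0.1))
    # no retained pair violates the threshold
    for (i in seq_along(kept)) for (j in seq_len(i - 1L)) {
      r <- suppressWarnings(cor(g[kept[i], ], g[kept[j], ],
                                use = "pairwise.complete.obs"))
      if (!is.na(r)) expect_lte(r^2, 0.1)
    }
  }
})

test_that("PCA separates drifted populations and is order-invariant", {
  cfg <- sim_config(n_chrom = 1L, chrom_length = 5e5,
                    n_snps_per_chrom = 500L,
                    pops = data.frame(label = c("P1", "P2"),
                                      role = c("focal", "contrast"),
                                      n = 15L, F = 0.3),
                    missing_rate = 0.02, seed = 31L)
  sim <- simulate_dataset(cfg)
  pca <- pca_genotypes(sim$gm, n_components = 4L)
  grp <- unname(sim$popmap$assignments[rownames(pca$coords)])
  pc1 <- pca$coords[, 1L]
  expect_true(max(pc1[grp == "P1"]) < min(pc1[grp == "P2"]) ||
                max(pc1[grp == "P2"]) < min(pc1[grp == "P1"]))
  expect_lte(sum(pca$explained), 1)

  # sample reordering leaves coordinates unchanged (up to row order)
  perm <- sample(n_samples(sim$gm))
  pca2 <- pca_genotypes(subset_gm(sim$gm, samples = perm), 4L)
  expect_equal(pca2$coords[rownames(pca$coords), ], pca$coords,
               tolerance = 1e-8)

  expect_error(pca_genotypes(sim$gm, n_components = 1000L), "n_components")
})

test_that("duplicated samples get identical PCA coordinates", {
  set.seed(41)
  g <- matrix(sample(0:2, 40 * 6, replace = TRUE), nrow = 40)
  g <- cbind(g, g[, 3L])
  gm <- make_gm(g, samples = c(paste0("S", 1:6), "S3dup"))
  pca <- pca_genotypes(gm, 2L)
  expect_equal(pca$coords["S3", ], pca$coords["S3dup", ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("1 - IBS distances follow the definition", {
  gm <- make_gm(cbind(c(0L, 1L), c(0L, 1L), c(2L, 1L), c(1L, 1L)),
                samples = c("a", "b", "c", "d"))
  d <- pairwise_distance(gm)
  expect_equal(d["a", "b"], 0)                     # identical samples
  expect_equal(d["a", "d"], 0.25)                  # (0.5 + 1)/2 -> 0.75 IBS
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  gm2 <- make_gm(cbind(c(0L, 0L), c(2L, 2L)), samples = c("x", "y"))
  expect_equal(pairwise_distance(gm2)["x", "y"], 1)  # opposite homozygotes

  gm3 <- make_gm(cbind(c(0L, NA), c(NA, 2L)), samples = c("x", "y"))
  expect_error(pairwise_distance(gm3), "no shared non-missing sites")
})

test_that("NJ recovers additive trees exactly", {
  # 4 taxa with known additive distances
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  d <- cophenetic(tr)
  out <- nj_tree(d, "D")
  expect_equal(cophenetic(out)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  out3 <- nj_tree(d3, "C")
  expect_equal(cophenetic(out3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-10)
  expect_error(nj_tree(d3[1:2, 1:2], "A"), "at least 3")
  expect_error(nj_tree(d3, "Z"), "not in")
})

test_that("NJ topology agrees with a brute-force Q-criterion oracle", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 6L
    labs <- letters[1:n]
    p <- matrix(runif(n * 4), n)
    d <- as.matrix(dist(p))
    dimnames(d) <- list(labs, labs)
    mine <- ape::unroot(nj_tree(d, "a"))
    oracle <- nj_oracle(d)
    expect_equal(ape::dist.topo(mine, oracle), 0, ignore_attr = TRUE)
    expect_equal(cophenetic(mine)[labs, labs], cophenetic(oracle)[labs, labs],
                 tolerance = 1e-6)
  }
})

test_that("bootstrap support is deterministic and finds real splits", {
  cfg <- sim_config(n_chrom = 1L, chrom_length = 3e5,
                    n_snps_per_chrom = 300L,
                    pops = data.frame(label = c("P1", "P2", "OUT"),
                                      role = c("focal", "contrast",
                                               "outgroup"),
                                      n = c(6L, 6L, 4L), F = 0.3),
                    missing_rate = 0, seed = 51L)
  sim <- simulate_dataset(cfg)
  root <- pop_samples(sim$popmap, "OUT")[1L]
  tr1 <- bootstrap_support(sim$gm, root, n_reps = 25L, seed = 99L)
  tr2 <- bootstrap_support(sim$gm, root, n_reps = 25L, seed = 99L)
  expect_identical(tr1$node.label, tr2$node.label)

  # the clade collecting population P1 is strongly supported
  tips_p1 <- pop_samples(sim$popmap, "P1")
  node <- ape::getMRCA(tr1, tips_p1)
  clade <- ape::extract.clade(tr1, node)
  expect_setequal(clade$tip.label, tips_p1)
  supp <- as.integer(tr1$node.label[node - ape::Ntip(tr1)])
  expect_gte(supp, 95L)

  # a single replicate can only produce 0 or 100
  tr0 <- bootstrap_support(sim$gm, root, n_reps = 1L, seed = 1L)
  lab <- tr0$node.label[tr0$node.label != ""]
  expect_true(all(lab %in% c("0", "100")))
})

test_that("negative branch lengths are clamped only at serialization", {
  tr <- ape::read.tree(text = "((A:1,B:-0.5):1,C:2);")
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  reread <- ape::read.tree(path)
  expect_true(all(reread$edge.length >= 0))
  expect_equal(min(tr$edge.length), -0.5)  # original object untouched
})
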