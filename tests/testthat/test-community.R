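test_that("mean-abundance filter applies the <1 observation rule", {
  # an ASV totalling 40 counts over 43 samples has mean 0.93 and is removed
  counts <- matrix(0L, nrow = 2, ncol = 43,
                   dimnames = list(c("low", "high"), paste0("s", 1:43)))
  counts["low", 1:40] <- 1L
  counts["high", ] <- 2L
  tab <- abundance_table(counts, as.Date("2016-10-13") + 14 * 0:42, rep("A", 43))
  kept <- filter_low_abundance(tab)
  expect_identical(rownames(kept$counts), "high")

  tab2 <- tiny_table()   # asv3 has count 1 everywhere: mean exactly 1, kept
  kept2 <- filter_low_abundance(tab2)
  expect_true("asv3" %in% rownames(kept2$counts))
  expect_identical(rownames(kept2$counts),
                   names(which(rowMeans(tab2$counts) >= 1)))
  expect_error(filter_low_abundance(tab, min_mean = 1000), "all ASVs removed")
})

test_that("relative abundances normalize each sample to 1", {
  m <- matrix(c(2, 2, 5, 0, 1, 3), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  rel <- relative_abundance(m)
  expect_equal(unname(rel[, 1]), c(0.5, 0.5))
  expect_equal(unname(colSums(rel)), rep(1, 3))
  m2 <- matrix(c(1, 0), ncol = 2, dimnames = list("a", c("s1", "s2")))
  expect_error(relative_abundance(m2), "empty sample")
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  m <- matrix(c(1, 1, 0,
                0, 2, 0), ncol = 2,
              dimnames = list(c("t1", "t2", "t3"), c("x", "y")))
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 0.5)        # (1+1)/(1+3)
  expect_equal(d["x", "x"], 0)

  set.seed(5)
  mm <- matrix(rpois(60, 10), nrow = 6,
               dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  expect_equal(unname(bray_curtis(mm)[lower.tri(matrix(0, 10, 10))]),
               unname(as.vector(vegan::vegdist(t(mm), method = "bray"))),
               tolerance = 1e-12)
  # invariance to common rescaling of both samples
  expect_equal(unclass(bray_curtis(mm)), unclass(bray_curtis(mm * 7)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identical and disjoint supports
  md <- matrix(c(3, 0, 0, 4), nrow = 2, dimnames = list(NULL, c("p", "q")))
  expect_equal(bray_curtis(md)["p", "q"], 1)
})

test_that("hierarchical clustering respects pair structure and ultrametricity", {
  d <- matrix(c(0, 0.1, 0.9, 0.9,
                0.1, 0, 0.9, 0.9,
                0.9, 0.9, 0, 0.2,
                0.9, 0.9, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- hierarchical_cluster(d)
  # the first two merges are the within-pair merges
  expect_true(all(hc$merge[1, ] < 0) && all(hc$merge[2, ] < 0))
  expect_equal(sort(hc$height[1:2]), c(0.1, 0.2))
  coph <- as.matrix(stats::cophenetic(hc))
  # input is ultrametric except the cross-pair distances, which are equal
  expect_equal(coph[order(rownames(coph)), order(colnames(coph))], d)

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$height, 0.3)
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("PCoA recovers a planar configuration up to rigid motion", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  rownames(pts) <- paste0("s", 1:4)
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  got <- as.matrix(res$scores[, c("Axis1", "Axis2")])
  # Procrustes: align via SVD of the cross-product of centered configs
  ctr <- scale(pts, scale = FALSE)
  sv <- svd(t(got) %*% ctr)
  aligned <- got %*% sv$u %*% t(sv$v)
  expect_lt(max(abs(aligned - ctr)), 1e-8)
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-12)
})

test_that("PCoA handles simplex and two-point degenerate geometries", {
  n <- 5
  d <- matrix(1, n, n) - diag(n)
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- pcoa(d)
  pos <- res$eigenvalues[res$eigenvalues > 1e-8]
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-8)

  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res2 <- pcoa(d2)
  expect_equal(sort(abs(res2$scores$Axis1)), c(1, 1), tolerance = 1e-9)
})

test_that("PERMANOVA permutation p matches exhaustive enumeration", {
  set.seed(11)
  x <- c(rnorm(3, 0), rnorm(3, 2))
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("g1", "g2"), each = 3)
  res <- permanova(d, groups, exact = TRUE)
  oracle <- permanova_oracle(d, groups)
  expect_equal(res$pseudo_f, oracle$f, tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(res$n_perm, oracle$n_arrangements)
  # pseudo-F agrees with the reference implementation in vegan
  veg <- vegan::adonis2(stats::as.dist(d) ~ g, data = data.frame(g = groups),
                        permutations = 5)
  expect_equal(res$pseudo_f, veg$F[1], tolerance = 1e-10)
  expect_equal(res$r2, veg$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA p hits the floor for perfectly separated groups", {
  # 3 groups of 4: the chance a sampled relabelling reproduces the exact
  # partition (the only way to match the infinite pseudo-F) is negligible
  n <- 12
  g <- rep(c("a", "b", "c"), each = 4)
  d <- matrix(1, n, n)
  for (lev in unique(g)) d[g == lev, g == lev] <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- permanova(d, g, n_perm = 99, seed = 2L)
  expect_equal(res$p_value, 1 / 100)
  # reproducible given the seed
  res2 <- permanova(d, g, n_perm = 99, seed = 2L)
  expect_identical(res$p_value, res2$p_value)
})

test_that("core microbiome membership uses the ceiling prevalence rule", {
  counts <- matrix(0L, 3, 43, dimnames = list(c("all", "b34", "b35"),
                                              paste0("s", 1:43)))
  counts["all", ] <- 1L
  counts["b34", 1:34] <- 1L   # 34/43 = 79.1% < 80%: excluded
  counts["b35", 1:35] <- 1L   # 35/43 = 81.4%: included (ceil(0.8*43) = 35)
  tab <- abundance_table(counts, as.Date("2020-01-01") + 0:42, rep("A", 43))
  core <- core_microbiome(tab, 0.80)
  expect_true(all(c("all", "b35") %in% core$core_ids))
  expect_false("b34" %in% core$core_ids)
  expect_equal(core$read_fraction,
               sum(counts[c("all", "b35"), ]) / sum(counts))
})
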