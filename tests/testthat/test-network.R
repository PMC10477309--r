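test_that("bicor handles exact linear relations and outliers", {
  x <- as.numeric(1:20)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -2 * x + 5), -1, tolerance = 1e-12)

  y <- x; y[20] <- 1000
  expect_equal(bicor(x, y), bicor_oracle(x, y), tolerance = 1e-12)
  expect_gt(bicor(x, y), cor(x, y))   # robust to the single outlier
})

test_that("bicor matches its definitional oracle on irregular data", {
  set.seed(31)
  for (i in 1:5) {
    x <- rlnorm(15); y <- 0.5 * x + rlnorm(15)
    expect_equal(bicor(x, y), bicor_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("bicor degenerates to Pearson when the MAD is zero", {
  x <- c(rep(1, 8), 2, 3)        # median absolute deviation is 0
  y <- rnorm(10)
  expect_warning(r <- bicor(x, y), "MAD is zero")
  # the x side is Pearson-standardized; with Gaussian y the weights differ,
  # so compare against a mixed-oracle: exact equality holds when both fall back
  x2 <- c(rep(0, 8), 1, -1)
  expect_warning(expect_warning(r2 <- bicor(x, x2)))
  expect_equal(r2, cor(x, x2), tolerance = 1e-12)
})

test_that("bicor tracks Pearson closely on well-behaved Gaussian data", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(200); y <- 0.6 * x + 0.8 * rnorm(200)
    expect_lt(abs(bicor(x, y) - cor(x, y)), 0.05)
  }
})

test_that("correlation t-test reproduces hand values and edge cases", {
  r0 <- correlation_test(0, 10)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1); expect_equal(r0$df, 8)

  r1 <- correlation_test(0.5, 4)
  expect_equal(r1$t, 0.5 * sqrt(2) / sqrt(0.75), tolerance = 1e-12)
  expect_equal(r1$p, 2 * pt(-r1$t, 2), tolerance = 1e-12)

  r2 <- correlation_test(1, 5)
  expect_equal(r2$p, 0); expect_true(r2$exact)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
})

test_that("CLR transform is centered and scale-invariant", {
  m <- matrix(5, nrow = 4, ncol = 2,
              dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  expect_true(all(clr_transform(m) == 0))

  set.seed(2)
  counts <- matrix(rpois(30, 20), nrow = 5)
  # doubling a sample's counts leaves its CLR essentially unchanged (exactly,
  # as the pseudocount becomes negligible)
  x <- matrix(c(2, 3, 5), ncol = 1)
  pc <- 1e-9
  expect_equal(clr_transform(2 * x, pc), clr_transform(x, pc), tolerance = 1e-6)
  # 3-part hand case
  v <- matrix(c(1, 3, 8), ncol = 1)
  g <- exp(mean(log(v + 1)))
  expect_equal(as.vector(clr_transform(v, 1)), as.vector(log((v + 1) / g)),
               tolerance = 1e-12)
  expect_equal(colSums(clr_transform(counts)), rep(0, 6), tolerance = 1e-9)
})

test_that("network nodes respect the prevalence threshold", {
  set.seed(4)
  counts <- matrix(rpois(40 * 40, 5) + 1L, nrow = 40,
                   dimnames = list(sprintf("a%02d", 1:40), sprintf("s%02d", 1:40)))
  counts[1, ] <- 0L; counts[1, 1:9] <- 5L    # 9/40 = 22.5% prevalence
  counts[2, ] <- 0L; counts[2, 1:10] <- 5L   # 10/40 = 25% prevalence
  tab <- abundance_table(counts, as.Date("2020-01-01") + 0:39, rep("A", 40))
  # a02 is zero in 3/4 of samples, so its MAD is zero and bicor warns about
  # the Pearson fallback — expected for sparse boundary nodes
  expect_warning(net <- build_network(tab, network_config(fdr_alpha = 0.05)),
                 "MAD is zero")
  expect_false("a01" %in% net$nodes$asv_id)
  expect_true("a02" %in% net$nodes$asv_id)
})

test_that("a planted module edge is recovered and inference is deterministic", {
  blocks <- tibble::tibble(label = "A", start = 1L, end = 60L)
  sc <- simulation_scenario(
    60, 40, blocks,
    guild_modules = list(list(members = 1:2,
                              guilds = c("hydrogenotrophic_methanogen", "syntroph"),
                              rho = 0.9, config = NA, log2_fc = 0)),
    depth = 20000, seed = 13L)
  sim <- simulate_timeseries(sc)
  net1 <- build_network(sim$table, network_config())
  net2 <- build_network(sim$table, network_config())
  expect_identical(net1$edges, net2$edges)
  key <- paste(net1$edges$from, net1$edges$to)
  expect_true(paste("ASV_001", "ASV_002") %in% key)
})

test_that("realized edge FDR stays near the nominal level with planted signal", {
  # the bicor + t-test + BH edge rule on 50 variables with 3 planted
  # correlated pairs; discoveries pooled over 50 seeded runs; data kept
  # non-compositional so the only dependence is the planted one
  alpha <- 0.05
  false_hits <- 0; hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n <- 40; p <- 50
    X <- matrix(rnorm(n * p), n, p)
    for (i in 1:3) {   # pair (2i-1, 2i) shares a factor: correlation 0.9
      f <- rnorm(n)
      X[, 2 * i - 1] <- sqrt(0.9) * f + sqrt(0.1) * X[, 2 * i - 1]
      X[, 2 * i] <- sqrt(0.9) * f + sqrt(0.1) * X[, 2 * i]
    }
    r <- bicor_matrix(X)
    idx <- which(upper.tri(r), arr.ind = TRUE)
    st <- correlation_test(r[upper.tri(r)], n)
    q <- bh_adjust(st$p)
    keep <- q < alpha & st$r > 0
    key <- paste(idx[keep, 1], idx[keep, 2])
    tkey <- paste(c(1, 3, 5), c(2, 4, 6))
    hits <- hits + sum(keep)
    false_hits <- false_hits + sum(!key %in% tkey)
  }
  expect_gt(hits, 100)                      # planted edges are found
  expect_lte(false_hits / max(hits, 1), 1.5 * alpha)
})

test_that("average clustering coefficient matches triangle enumeration", {
  tri <- cooc_network(tibble::tibble(asv_id = c("a", "b", "c")),
                      tibble::tibble(from = c("a", "a", "b"),
                                     to = c("b", "c", "c"), weight = rep(1, 3)))
  expect_equal(avg_clustering_coefficient(tri), 1)

  star <- cooc_network(tibble::tibble(asv_id = c("h", "x", "y", "z")),
                       tibble::tibble(from = rep("h", 3), to = c("x", "y", "z"),
                                      weight = rep(1, 3)))
  expect_equal(avg_clustering_coefficient(star), 0)

  net <- fixture_network()
  expect_equal(avg_clustering_coefficient(net),
               clustering_oracle(net$edges, net$nodes$asv_id))
  # alternative convention: drop degree-<2 nodes from the mean
  expect_equal(avg_clustering_coefficient(net, exclude_low_degree = TRUE),
               mean(c(1, 1, 1 / 3)))   # a, b, c; d has degree 1, e degree 0
})

test_that("glasso path is empty at lambda_max and monotone along the path", {
  set.seed(10)
  X <- matrix(rnorm(50 * 6), 50, 6)
  X[, 2] <- X[, 1] + 0.3 * rnorm(50)
  S <- cov(X)
  lams <- lambda_path(S, 0.1, 10)
  sizes <- integer(10)
  prev_edges <- NULL
  for (i in seq_along(lams)) {
    f <- glasso_fit(S, lams[i])
    adj <- f$partial_cor != 0
    sizes[i] <- sum(adj[upper.tri(adj)])
    if (!is.null(prev_edges)) {
      expect_true(all(prev_edges[upper.tri(prev_edges)] <= adj[upper.tri(adj)]))
    }
    prev_edges <- adj
  }
  expect_equal(sizes[1], 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("glasso with StARS recovers a 3-block dependence structure", {
  set.seed(3)
  p <- 9; n <- 200; rhos <- c(0.75, 0.55, 0.35)
  Sigma <- diag(p)
  for (b in 0:2) {
    idx <- b * 3 + 1:3
    Sigma[idx, idx] <- rhos[b + 1]; diag(Sigma)[idx] <- 1
  }
  X <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
  colnames(X) <- paste0("V", 1:p)
  cfg <- network_config(edge_method = "clr_glasso", positive_edges_only = FALSE,
                        seed = 13L)
  net <- sparse_precision_network(t(X), cfg)
  truth <- do.call(rbind, lapply(0:2, function(b) t(combn(b * 3 + 1:3, 2))))
  tkey <- paste0("V", truth[, 1], "_V", truth[, 2])
  ekey <- paste0(net$edges$from, "_", net$edges$to)
  expect_setequal(ekey, tkey)   # precision and recall both 1
})

test_that("glasso network on independent data stays near-empty", {
  set.seed(4)
  Y <- matrix(rnorm(200 * 30), 200, 30)
  colnames(Y) <- paste0("V", 1:30)
  cfg <- network_config(edge_method = "clr_glasso", positive_edges_only = FALSE,
                        seed = 5L)
  net <- sparse_precision_network(t(Y), cfg)
  expect_lt(nrow(net$edges) / choose(30, 2), 0.02)
})
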