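# in-code fixtures shared across test files

# 5 ASVs x 6 samples with easily hand-checked structure
tiny_table <- function() {
  counts <- matrix(
    c(10, 12,  8, 11,  9, 10,   # ubiquitous, high
       0,  0,  5,  6,  7,  8,   # present in second half
       1,  1,  1,  1,  1,  1,   # boundary: mean exactly 1
       0,  0,  0,  1,  0,  0,   # rare
       3,  0,  4,  0,  5,  0),  # alternating
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("asv", 1:5), paste0("s", 1:6)))
  abundance_table(counts,
                  sample_dates = as.Date("2020-01-01") + 14 * 0:5,
                  configuration = rep(c("A", "B"), each = 3))
}

# small network with a triangle plus a pendant
fixture_network <- function() {
  nodes <- tibble::tibble(
    asv_id = c("a", "b", "c", "d", "e"),
    guild = c("hydrogenotrophic_methanogen", "syntroph", "syntroph",
              "other", "other"))
  edges <- tibble::tibble(
    from = c("a", "a", "b", "c"),
    to = c("b", "c", "c", "d"),
    weight = c(0.9, 0.8, 0.7, 0.6))
  cooc_network(nodes, edges)
}

# definitional biweight midcorrelation, written independently of the
# package implementation (scalar loops, no shared helpers)
bicor_oracle <- function(x, y) {
  tf <- function(v) {
    med <- sort(v)[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0) med <- mean(sort(v)[length(v) / 2 + 0:1])
    dev <- v - med
    mad0 <- sort(abs(dev))[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0) mad0 <- mean(sort(abs(dev))[length(v) / 2 + 0:1])
    u <- dev / (9 * mad0)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    a <- dev * w
    a / sqrt(sum(a^2))
  }
  sum(tf(x) * tf(y))
}

# natural cubic spline evaluated from the textbook tridiagonal system,
# independent of stats::splinefun
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # second derivatives M solve a tridiagonal system; natural ends M1=Mn=0
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  M <- solve(A, b)
  vapply(xout, function(q) {
    i <- findInterval(q, x, rightmost.closed = TRUE)
    i <- min(max(i, 1), n - 1)
    t1 <- x[i + 1] - q; t2 <- q - x[i]
    (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2
  }, numeric(1))
}

# brute-force average clustering coefficient by triangle enumeration
clustering_oracle <- function(edges, node_ids) {
  adj <- matrix(FALSE, length(node_ids), length(node_ids),
                dimnames = list(node_ids, node_ids))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  local <- vapply(node_ids, function(v) {
    nb <- node_ids[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (adj[nb[i], nb[j]]) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

# exhaustive PERMANOVA oracle: pseudo-F over every distinct labelling,
# computed from scratch (plain double loops over the distance matrix)
permanova_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- as.character(groups)
  f_of <- function(g) {
    ss_t <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
    ss_t <- ss_t / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        s <- 0
        for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
          s <- s + d[idx[a], idx[b]]^2
        }
        ss_w <- ss_w + s / length(idx)
      }
    }
    a <- length(unique(g))
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  obs <- f_of(labs)
  # enumerate all distinct arrangements of the label multiset
  arrangements <- unique(combinat_perms(labs))
  fs <- vapply(arrangements, f_of, numeric(1))
  list(f = obs, p = mean(fs >= obs - 1e-12), n_arrangements = length(arrangements))
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (p in combinat_perms(rest)) out[[length(out) + 1]] <- c(u, p)
  }
  out
}

# exhaustive subset search for the environment-community rank correlation,
# independent loops (no shared code with the implementation)
bioenv_oracle <- function(d, params) {
  d <- as.matrix(d)
  cd <- d[lower.tri(d)]
  z <- scale(params)
  best <- list(rho = -Inf, subset = NULL)
  all_rows <- list()
  for (size in 1:ncol(params)) {
    for (cb in utils::combn(ncol(params), size, simplify = FALSE)) {
      n <- nrow(z)
      ed <- matrix(0, n, n)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        ed[i, j] <- ed[j, i] <- sqrt(sum((z[i, cb] - z[j, cb])^2))
      }
      rho <- cor(cd, ed[lower.tri(ed)], method = "spearman")
      key <- paste(colnames(params)[cb], collapse = "+")
      all_rows[[key]] <- rho
      if (rho > best$rho) best <- list(rho = rho, subset = key)
    }
  }
  list(best = best, all = unlist(all_rows))
}

# multivariate hypergeometric joint tail by explicit enumeration of subsets
enrichment_enum_oracle <- function(guilds, k, s, m, mode = "at_least") {
  subsets <- utils::combn(length(guilds), k, simplify = FALSE)
  ok <- vapply(subsets, function(idx) {
    si <- sum(guilds[idx] == "syntroph")
    mi <- sum(guilds[idx] == "hydrogenotrophic_methanogen")
    if (mode == "at_least") si >= s && mi >= m else si == s && mi == m
  }, logical(1))
  mean(ok)
}
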