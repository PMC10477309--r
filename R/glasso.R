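#' Graphical lasso estimate of a sparse precision matrix
#'
#' L1-penalized Gaussian inverse-covariance estimation by blockwise
#' coordinate descent (compiled): each column of the working covariance
#' `W` is updated by solving a lasso regression against the remaining
#' variables until `W` stabilizes, after which the precision matrix is
#' recovered from the regression coefficients. Nonzero off-diagonal
#' precision entries are conditional-dependence edges.
#'
#' @param S Sample covariance matrix.
#' @param rho Penalty (>= 0).
#' @param tol Relative convergence tolerance on the off-diagonal of `W`.
#' @param max_iter Maximum outer sweeps.
#' @param warm Optional warm start: a previous fit's `W`/`B` (used when
#'   walking a penalty path).
#' @return List: `precision`, `covariance` (the penalized estimate),
#'   `partial_cor` (sign-carrying partial correlations, zero diagonal),
#'   `converged`, plus `W`/`B` for warm starts.
#' @export
glasso_fit <- function(S, rho, tol = 1e-4, max_iter = 100, warm = NULL) {
  S <- as.matrix(S)
  p <- ncol(S)
  stopifnot(isSymmetric(unname(S)), rho >= 0)
  if (p == 1) {
    return(list(precision = matrix(1 / (S[1, 1] + rho)), covariance = S + rho,
                partial_cor = matrix(0), converged = TRUE,
                W = S + rho, B = matrix(0, 1, 1)))
  }
  W0 <- if (is.null(warm)) { W <- S; diag(W) <- diag(S) + rho; W } else warm$W
  B0 <- if (is.null(warm)) matrix(0, p, p) else warm$B
  fit <- .glasso_cd(S, rho, W0, B0, tol, as.integer(max_iter), 1e-6, 500L)
  W <- fit$W; B <- fit$B
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    theta_jj <- 1 / (W[j, j] - sum(W[-j, j] * B[-j, j]))
    Theta[j, j] <- theta_jj
    Theta[-j, j] <- -B[-j, j] * theta_jj
  }
  # exact zeros from the soft threshold define the support; require
  # agreement of the two column solves, then symmetrize values
  support <- (Theta != 0) & (t(Theta) != 0)
  diag(support) <- TRUE
  Theta <- (Theta + t(Theta)) / 2 * support
  d <- sqrt(diag(Theta))
  pc <- -Theta / tcrossprod(d)
  diag(pc) <- 0
  dimnames(Theta) <- dimnames(pc) <- dimnames(S)
  list(precision = Theta, covariance = W, partial_cor = pc,
       converged = fit$converged, W = W, B = B)
}

#' Penalty path for the graphical lasso
#'
#' Log-spaced grid from `lambda_max` (the largest absolute off-diagonal
#' covariance, at which the estimated graph is empty) down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param S Covariance matrix.
#' @param lambda_min_ratio,n_lambda Grid parameters.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(S, lambda_min_ratio = 0.1, n_lambda = 20) {
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max == 0) stop("covariance has no off-diagonal signal", call. = FALSE)
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = n_lambda))
}

# adjacency matrices along a penalty path (warm-started from the sparse
# end); lambdas for which the solver did not converge are dropped with a
# warning
glasso_path <- function(S, lambdas) {
  fits <- vector("list", length(lambdas))
  warm <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- glasso_fit(S, lambdas[i], warm = warm)
    warm <- fits[[i]]
  }
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(ok)) {
    warning(sum(!ok), " penalty value(s) dropped: solver did not converge")
  }
  list(lambdas = lambdas[ok],
       adjacency = lapply(fits[ok], function(f) f$partial_cor != 0),
       fits = fits[ok])
}

#' Select the penalty by edge stability (StARS)
#'
#' Fits the penalty path on repeated subsamples of the data and measures,
#' for each penalty, the edge instability `mean over pairs of
#' 2 xi (1 - xi)` where `xi` is the fraction of subsamples containing the
#' edge. The instability curve is monotonized from the sparse end and the
#' densest penalty whose monotonized instability stays at or below the
#' threshold is selected.
#'
#' @param data Samples x variables matrix.
#' @param lambdas Decreasing penalty grid (see [lambda_path()]).
#' @param n_subsamples,subsample_size,threshold,seed StARS parameters.
#' @return List: `lambda_opt`, `opt_index`, `instability` (per lambda),
#'   `lambdas`.
#' @export
stars_select <- function(data, lambdas, n_subsamples = 20,
                         subsample_size = NULL, threshold = 0.05, seed = 1L) {
  n <- nrow(data); p <- ncol(data)
  if (is.null(subsample_size)) subsample_size <- min(n, floor(10 * sqrt(n)))
  set.seed(seed)
  n_pairs <- choose(p, 2)
  freq <- matrix(0, length(lambdas), n_pairs)
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, subsample_size)
    Sb <- stats::cov(data[idx, , drop = FALSE])
    pb <- glasso_path(Sb, lambdas)
    hit <- match(signif(pb$lambdas, 12), signif(lambdas, 12))
    for (i in seq_along(pb$lambdas)) {
      freq[hit[i], ] <- freq[hit[i], ] + pb$adjacency[[i]][upper.tri(pb$adjacency[[i]])]
    }
  }
  xi <- freq / n_subsamples
  instability <- rowMeans(2 * xi * (1 - xi))
  mono <- cummax(instability)
  ok <- which(mono <= threshold)
  opt <- if (length(ok) > 0) max(ok) else 1L
  list(lambda_opt = lambdas[opt], opt_index = opt,
       instability = instability, lambdas = lambdas)
}

#' Co-occurrence network from sparse inverse covariance
#'
#' Estimates a graphical-lasso solution path on the covariance of
#' CLR-transformed abundances, selects the penalty by StARS, and returns
#' the conditional-dependence graph at the selected penalty with
#' sign-carrying partial correlations as edge weights.
#'
#' @param clr CLR-transformed matrix, taxa x samples (see
#'   [clr_transform()]).
#' @param cfg A [network_config()] (uses the glasso/StARS fields).
#' @param node_info Optional node tibble (`asv_id`, annotations) to carry
#'   through; defaults to the CLR rownames.
#' @return A [cooc_network()] with attributes `"lambda_opt"`,
#'   `"stars"` (the [stars_select()] result).
#' @export
sparse_precision_network <- function(clr, cfg = network_config(edge_method = "clr_glasso"),
                                     node_info = NULL) {
  data <- t(as.matrix(clr))
  if (nrow(data) < 4) stop("need at least 4 samples", call. = FALSE)
  ids <- colnames(data)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(data)))
  S <- stats::cov(data)
  lambdas <- lambda_path(S, cfg$lambda_min_ratio, cfg$n_lambda)
  sel <- stars_select(data, lambdas, n_subsamples = cfg$stars_subsamples,
                      subsample_size = cfg$stars_subsample_size,
                      threshold = cfg$stars_threshold, seed = cfg$seed)
  fit <- glasso_fit(S, sel$lambda_opt)
  pc <- fit$partial_cor
  idx <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  edges <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                          weight = pc[idx], p = NA_real_, q = NA_real_)
  if (cfg$positive_edges_only) edges <- edges[edges$weight > 0, ]
  nodes <- if (is.null(node_info)) tibble::tibble(asv_id = ids) else node_info
  net <- cooc_network(nodes, edges, positive_only = cfg$positive_edges_only)
  attr(net, "lambda_opt") <- sel$lambda_opt
  attr(net, "stars") <- sel
  net
}
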