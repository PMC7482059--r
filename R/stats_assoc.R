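## Ordination, variance partitioning and community association for
## fermentation product profiles.

#' Euclidean distance matrix of product profiles
#'
#' @param profiles Numeric matrix, samples in rows, products in columns
#'   (mol per mol fiber). No missing values allowed.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 samples")
  if (anyNA(profiles)) stop("missing values in profiles")
  as.matrix(stats::dist(profiles, method = "euclidean"))
}

#' Principal-coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it
#' (via [stats::cmdscale()]); axes are ordered by eigenvalue. For a Euclidean
#' input all eigenvalues are nonnegative (up to roundoff) and the coordinate
#' distances reproduce the input.
#'
#' @param d Distance matrix (square symmetric) or `dist` object.
#' @return List with `coordinates` (samples x axes), `eigenvalues`, and
#'   `variance_fraction` (share of positive eigenvalue mass per axis).
#' @export
pcoa_products <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("d must be a square symmetric distance matrix")
  }
  n <- nrow(D)
  ## cmdscale warns when fewer than k axes have positive eigenvalues; the
  ## eigenvalue filtering below makes that informational only
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  ev <- fit$eig
  pos <- ev > 1e-12 * max(abs(ev), 1)
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  keep <- seq_len(min(ncol(coords), sum(pos)))
  coords <- coords[, keep, drop = FALSE]
  if (ncol(coords) == 0L) coords <- matrix(0, n, 1) # all points coincident
  colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  vf <- rep(0, length(ev))
  if (any(pos)) vf[pos] <- ev[pos] / sum(ev[pos])
  list(coordinates = coords, eigenvalues = ev,
       variance_fraction = vf[seq_len(ncol(coords))])
}

## hat matrix of a model matrix
.hat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (order-as-given) partitioning of the Gower-centered distance
#' matrix among factors, after McArdle & Anderson: G = -1/2 J D^2 J, the sum
#' of squares for each term is tr((H_k - H_(k-1)) G) for the nested hat
#' matrices, and the pseudo-F compares each term to the full-model residual.
#' The p-value permutes sample labels: with `n_permutations` random draws,
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations); with
#' `exhaustive = TRUE` all n! orderings are enumerated and the p-value is the
#' exact fraction.
#'
#' When raw profiles are supplied, the per-product model coefficients (least
#' squares of the factor model matrix on the centered product columns) are
#' also returned: these identify which products separate the factor levels.
#'
#' @param d Distance matrix, or `NULL` to compute Euclidean distances from
#'   `profiles`.
#' @param factors Data frame (or named list) of factor vectors, in the order
#'   the variance should be attributed (e.g. fiber first, then subject).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Optional RNG seed for the permutations.
#' @param exhaustive Enumerate all orderings (only for small n).
#' @param profiles Optional samples x products matrix (used for distances when
#'   `d` is NULL, and for coefficients).
#' @return List with `table` (per-term df, SS, R2, pseudo-F, p), `residual_ss`,
#'   `total_ss`, and `coefficients` when profiles are given.
#' @examples
#' pr <- matrix(c(0, 2, 8, 10), ncol = 1)
#' permanova(factors = list(group = c("A", "A", "B", "B")),
#'           profiles = pr, exhaustive = TRUE)$table
#' @export
permanova <- function(d = NULL, factors, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE, profiles = NULL) {
  if (is.null(d)) {
    if (is.null(profiles)) stop("supply a distance matrix or profiles")
    d <- euclidean_distance_matrix(profiles)
  }
  D <- as.matrix(d)
  n <- nrow(D)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != n) stop("factors must cover all samples")
  for (f in names(factors)) {
    if (length(unique(factors[[f]])) < 2L) stop("factor ", f, " has a single level")
  }
  ## Gower-centered inner product matrix
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  ss_total <- sum(diag(G))

  terms <- names(factors)
  Xs <- list(matrix(1, n, 1))
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(~., data = factors[, seq_len(k), drop = FALSE])
    Xs[[k + 1L]] <- mm
  }
  hats <- lapply(Xs, .hat)
  df_terms <- vapply(seq_along(terms), function(k) {
    qr(Xs[[k + 1L]])$rank - qr(Xs[[k]])$rank
  }, 0L)
  if (sum(df_terms) >= n) stop("more model parameters than samples")
  H_full <- hats[[length(hats)]]
  df_res <- n - qr(Xs[[length(Xs)]])$rank

  stat <- function(Gm) {
    ss <- vapply(seq_along(terms), function(k) {
      sum(diag((hats[[k + 1L]] - hats[[k]]) %*% Gm))
    }, 0)
    ss_res <- sum(diag((diag(n) - H_full) %*% Gm))
    f <- (ss / df_terms) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat(G)

  if (exhaustive) {
    perms <- .permutations(n)
    f_perm <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stat(G[p, p])$f
    }, numeric(length(terms)))
    f_perm <- matrix(f_perm, ncol = length(terms), byrow = TRUE)
    p_vals <- colMeans(sweep(f_perm, 2, obs$f, ">=") |
                         abs(sweep(f_perm, 2, obs$f, "-")) < 1e-12)
    n_perm_used <- nrow(perms)
  } else {
    if (n_permutations < 1L) stop("n_permutations must be >= 1")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    count <- rep(0L, length(terms))
    for (i in seq_len(n_permutations)) {
      p <- sample.int(n)
      fp <- stat(G[p, p])$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    p_vals <- (1 + count) / (1 + n_permutations)
    n_perm_used <- n_permutations
  }

  tab <- data.frame(term = terms, df = df_terms, ss = obs$ss,
                    r2 = obs$ss / ss_total,
                    pseudo_f = obs$f, p_value = p_vals)
  out <- list(table = tab, residual_ss = obs$ss_res, residual_df = df_res,
              total_ss = ss_total, n_permutations = n_perm_used)
  if (!is.null(profiles)) {
    Y <- scale(as.matrix(profiles), center = TRUE, scale = FALSE)
    X <- Xs[[length(Xs)]]
    coefs <- qr.coef(qr(X), Y)
    out$coefficients <- coefs
  }
  out
}

## all permutations of 1..n (small n only)
.permutations <- function(n) {
  if (n > 8L) stop("exhaustive permutation only supported for n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Lasso association of community features with a response, with exact LOOCV
#'
#' L1-penalized least squares (coordinate descent via [glmnet::glmnet()],
#' convergence threshold 1e-7) over a log-spaced penalty grid; the penalty is
#' chosen by minimum leave-one-out mean squared error with exact refits (n is
#' small). Coefficients are reported on the original (unstandardized) scale.
#' The top feature (largest absolute standardized coefficient) is additionally
#' summarized by its Pearson correlation with the response.
#'
#' @param features Samples x taxa matrix of relative abundances (rows sum to
#'   approximately 1).
#' @param response Numeric response per sample (e.g. net H2 per mol inulin).
#' @param n_lambda Length of the penalty grid (default 100).
#' @param clr Optional centered-log-ratio transform of the features before
#'   fitting (off by default; the untransformed relative abundances are used).
#' @return An `association_result`: list with `selected` (named nonzero
#'   coefficients), `lambda` (chosen penalty), `lambda_grid`, `loo_mse`,
#'   `top_feature`, `top_cor` (list r, p), `intercept`. A constant response
#'   returns an empty selection, not an error.
#' @export
lasso_loocv <- function(features, response, n_lambda = 100, clr = FALSE) {
  X <- as.matrix(features)
  y <- as.numeric(response)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  if (length(y) != n) stop("response length must match rows of features")
  if (stats::sd(y) == 0) {
    return(structure(list(selected = numeric(0), lambda = NA_real_,
                          lambda_grid = numeric(0), loo_mse = numeric(0),
                          top_feature = NA_character_, top_cor = NULL,
                          intercept = mean(y)),
                     class = "association_result"))
  }
  if (clr) {
    pseudo <- min(X[X > 0]) / 2
    L <- log(X + pseudo)
    X <- L - rowMeans(L)
  }
  fit_full <- glmnet::glmnet(X, y, family = "gaussian", nlambda = n_lambda,
                             thresh = 1e-7)
  grid <- fit_full$lambda
  errs <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    fit_i <- glmnet::glmnet(X[-i, , drop = FALSE], y[-i], family = "gaussian",
                            lambda = grid, thresh = 1e-7)
    pred <- stats::predict(fit_i, newx = X[i, , drop = FALSE])
    errs[i, seq_len(ncol(pred))] <- (pred - y[i])^2
  }
  loo_mse <- colMeans(errs)
  best <- which.min(loo_mse)
  lambda <- grid[best]
  beta <- as.numeric(stats::coef(fit_full, s = lambda))
  names(beta) <- c("(Intercept)", colnames(X))
  nz <- beta[-1][beta[-1] != 0]
  top_feature <- NA_character_
  top_cor <- NULL
  if (length(nz)) {
    sds <- apply(X[, names(nz), drop = FALSE], 2, stats::sd)
    top_feature <- names(nz)[which.max(abs(nz) * sds)]
    top_cor <- pearson_cor(X[, top_feature], y)
  }
  structure(list(selected = nz, lambda = lambda, lambda_grid = grid,
                 loo_mse = loo_mse, top_feature = top_feature,
                 top_cor = top_cor, intercept = beta[1]),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %d feature(s) selected at lambda = %.4g\n",
              length(x$selected), x$lambda))
  if (length(x$selected)) {
    print(round(x$selected, 5))
    cat(sprintf("  top feature %s: r = %.4f, p = %.3g\n",
                x$top_feature, x$top_cor$r, x$top_cor$p))
  }
  invisible(x)
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return List with `r`, `p` (two-sided, t transform with n - 2 df), `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' RPKM normalization of metagenome gene counts
#'
#' Reads per kilobase of gene per million sequenced reads:
#' count / ((length / 1000) * (depth / 1e6)). An optional pseudo-increment of
#' 1e-5 on the counts mirrors the log-scale plotting transform for samples
#' with zero hits; it is off by default.
#'
#' @param read_count Gene hit count (vectorized).
#' @param mean_gene_length_bp Average gene length in base pairs (> 0).
#' @param sequencing_depth_reads Total reads in the (rarefied) metagenome (> 0).
#' @param pseudo Add 1e-5 to the counts before normalizing (default FALSE).
#' @return RPKM value(s).
#' @examples
#' rpkm_normalize(40, 1000, 20e6) # 2
#' @export
rpkm_normalize <- function(read_count, mean_gene_length_bp,
                           sequencing_depth_reads, pseudo = FALSE) {
  if (any(mean_gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(sequencing_depth_reads <= 0)) stop("sequencing depth must be positive")
  if (any(read_count < 0)) stop("read counts must be nonnegative")
  if (pseudo) read_count <- read_count + 1e-5
  read_count / ((mean_gene_length_bp / 1000) * (sequencing_depth_reads / 1e6))
}
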