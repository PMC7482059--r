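test_that("euclidean distances behave as metric distances", {
  m <- rbind(c(0, 0), c(3, 4))
  expect_equal(euclidean_distance_matrix(m)[1, 2], 5)

  m2 <- rbind(c(1, 2), c(1, 2), c(4, 6))
  d2 <- euclidean_distance_matrix(m2)
  expect_equal(d2[1, 2], 0)

  set.seed(9)
  m3 <- matrix(rnorm(15), 5, 3)
  d3 <- euclidean_distance_matrix(m3)
  p <- sample(5)
  expect_equal(euclidean_distance_matrix(m3[p, ]), unname(d3[p, p]),
               ignore_attr = TRUE)
  expect_error(euclidean_distance_matrix(m3[1, , drop = FALSE]), "2 samples")
  m3[2, 2] <- NA
  expect_error(euclidean_distance_matrix(m3), "missing")
})

test_that("classical scaling recovers known configurations", {
  # collinear points at mutual distances 1, 1, 2: one positive axis
  D <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  p <- pcoa_products(D)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-9)

  # identical points are coincident in the ordination
  D2 <- rbind(c(0, 0), c(0, 0))
  p2 <- pcoa_products(D2)
  expect_equal(p2$coordinates[1, ], p2$coordinates[2, ], tolerance = 1e-10)

  # a 2D configuration is recovered isometrically: coordinate distances
  # reproduce the input and all eigenvalues are nonnegative
  set.seed(21)
  X <- matrix(rnorm(20), 10, 2)
  D3 <- euclidean_distance_matrix(X)
  p3 <- pcoa_products(D3)
  expect_gt(min(p3$eigenvalues), -1e-9)
  D3_hat <- euclidean_distance_matrix(p3$coordinates)
  expect_equal(unname(D3_hat), unname(D3), tolerance = 1e-8)

  expect_error(pcoa_products(matrix(1:6, 2, 3)), "square")
})

test_that("classical scaling agrees with the ape implementation", {
  set.seed(33)
  X <- matrix(rnorm(24), 8, 3)
  D <- euclidean_distance_matrix(X)
  ours <- pcoa_products(D)
  ref <- ape::pcoa(as.dist(D))
  k <- ncol(ref$vectors)
  for (j in seq_len(min(3, k))) {
    expect_equal(abs(ours$coordinates[, j]), abs(ref$vectors[, j]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(ours$eigenvalues[seq_len(3)], ref$values$Eigenvalues[seq_len(3)],
               tolerance = 1e-8)
})

test_that("variance partitioning matches the hand-computed worked example", {
  pr <- matrix(c(0, 2, 8, 10), ncol = 1)
  res <- permanova(factors = list(group = c("A", "A", "B", "B")),
                   profiles = pr, exhaustive = TRUE)
  expect_equal(res$table$ss, 64)
  expect_equal(res$table$r2, 64 / 68)
  expect_equal(res$table$pseudo_f, 32)
  expect_equal(res$table$p_value, 1 / 3) # 8 of 24 orderings reach F = 32
  expect_equal(res$total_ss, 68)
  expect_error(permanova(factors = list(g = rep("A", 4)), profiles = pr),
               "single level")
})

test_that("sequential R2 values and the residual sum to one", {
  set.seed(14)
  n <- 12
  profiles <- matrix(rnorm(n * 4), n)
  fac <- list(fiber = rep(c("inulin", "pectin"), each = 6),
              subject = rep(paste0("S", 1:6), 2))
  res <- permanova(factors = fac, profiles = profiles, n_permutations = 49,
                   seed = 2)
  expect_equal(sum(res$table$r2) + res$residual_ss / res$total_ss, 1,
               tolerance = 1e-9)
  expect_equal(res$table$term, c("fiber", "subject"))
})

test_that("variance partitioning agrees with vegan's sequential adonis", {
  set.seed(27)
  n <- 12
  profiles <- matrix(rnorm(n * 3), n)
  profiles[7:12, 1] <- profiles[7:12, 1] + 2
  fac <- data.frame(g = rep(c("a", "b"), each = 6),
                    h = rep(c("x", "y", "z"), 4))
  ours <- permanova(factors = fac, profiles = profiles, n_permutations = 99,
                    seed = 1)
  ref <- vegan::adonis2(profiles ~ g + h, data = fac, method = "euclidean",
                        by = "terms", permutations = 99)
  expect_equal(ours$table$r2, ref$R2[1:2], tolerance = 1e-9)
  expect_equal(ours$table$pseudo_f, ref$F[1:2], tolerance = 1e-9)
})

test_that("factor-level coefficients identify the separating products", {
  set.seed(5)
  n <- 10
  profiles <- matrix(rnorm(n * 3, sd = 0.1), n)
  colnames(profiles) <- c("H2", "acetate", "CO2")
  grp <- rep(c("inulin", "pectin"), each = 5)
  profiles[grp == "pectin", "acetate"] <- profiles[grp == "pectin", "acetate"] + 10
  res <- permanova(factors = list(fiber = grp), profiles = profiles,
                   n_permutations = 19, seed = 1)
  cf <- res$coefficients["fiberpectin", ]
  expect_equal(unname(cf["acetate"]), 10, tolerance = 0.2)
  expect_lt(max(abs(cf[c("H2", "CO2")])), 0.5)
})

test_that("permutation p-values are calibrated under the null", {
  # label permutations of pure-noise profiles: rejection rate at alpha = 0.05
  # must fall in the binomial 95% band
  set.seed(100)
  n_sim <- 200
  alpha <- 0.05
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    profiles <- matrix(rnorm(10 * 3), 10)
    fac <- list(g = rep(c("a", "b"), each = 5))
    p <- permanova(factors = fac, profiles = profiles, n_permutations = 99)$table$p_value
    rej[i] <- p <= alpha
  }
  band <- qbinom(c(0.025, 0.975), n_sim, alpha) / n_sim
  expect_gte(mean(rej), band[1])
  expect_lte(mean(rej), band[2])
})

test_that("lasso with exact LOOCV recovers a planted feature", {
  set.seed(8)
  n <- 30
  p <- 50
  X <- matrix(rlnorm(n * p, 0, 1), n)
  X <- X / rowSums(X)
  colnames(X) <- paste0("taxon_", seq_len(p))
  y <- 5 * X[, 17] + rnorm(n, sd = 0.01 * sd(5 * X[, 17]))
  res <- lasso_loocv(X, y)
  expect_true("taxon_17" %in% names(res$selected))
  expect_identical(res$top_feature, "taxon_17")
  expect_gt(res$top_cor$r, 0.99)
})

test_that("lasso coefficients obey the soft-threshold closed form", {
  # columns orthonormal under the 1/n inner product: the coordinate-descent
  # solution at penalty lambda is S(x_j'y/n, lambda) exactly
  set.seed(12)
  n <- 40
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x1 <- x1 - mean(x1)
  x2 <- residuals(lm(x2 ~ x1))
  x1 <- x1 / sqrt(mean(x1^2))
  x2 <- x2 / sqrt(mean(x2^2))
  X <- cbind(f1 = x1, f2 = x2)
  y <- 2 * x1 + 0.3 * x2 + rnorm(n, sd = 0.05)
  res <- lasso_loocv(X, y)
  lam <- res$lambda
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  expected <- soft(mean(x1 * (y - mean(y))), lam)
  expect_equal(unname(res$selected["f1"]), expected, tolerance = 1e-4)
})

test_that("degenerate lasso inputs give empty selections, not errors", {
  X <- matrix(runif(30), 10, 3)
  res <- lasso_loocv(X, rep(2, 10))
  expect_length(res$selected, 0)
  expect_error(lasso_loocv(X[1:2, ], 1:2), "3 samples")
})

test_that("pearson correlation and t-test p match hand computation", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  r <- pearson_cor(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(r$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-9)
  expect_equal(r$r, 0.9827, tolerance = 1e-4)
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "variance")
})

test_that("RPKM normalization follows the rate formula", {
  expect_equal(rpkm_normalize(40, 1000, 20e6), 2)
  expect_equal(rpkm_normalize(0, 500, 1e6), 0)
  expect_equal(rpkm_normalize(10, 1000, 40e6),
               rpkm_normalize(10, 1000, 20e6) / 2)
  expect_equal(rpkm_normalize(0, 1000, 20e6, pseudo = TRUE),
               1e-5 / (1 * 20))
  expect_error(rpkm_normalize(1, 0, 1e6), "length")
})
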