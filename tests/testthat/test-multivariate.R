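# independent spectral oracle: power iteration with deflation
power_eigen <- function(A, k = nrow(A), iters = 2000) {
  vals <- numeric(k)
  vecs <- matrix(0, nrow(A), k)
  M <- A
  for (i in seq_len(k)) {
    v <- rep(1 / sqrt(nrow(A)), nrow(A))
    for (it in seq_len(iters)) v <- {
      w <- M %*% v
      as.numeric(w / sqrt(sum(w^2)))
    }
    vals[i] <- as.numeric(t(v) %*% M %*% v)
    vecs[, i] <- v
    M <- M - vals[i] * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

test_that("correlation-mode eigenvalues match closed forms and the oracle", {
  # two perfectly correlated variables: rank-1 correlation matrix
  x <- c(1, 3, 2, 5, 4)
  res <- pca(cbind(a = x, b = 2 * x + 1))
  expect_equal(res$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(res$contribution_pct, c(100, 0), tolerance = 1e-10)
  expect_equal(res$n_nonzero, 1L)

  # equicorrelation rho = 0.5, p = 3: spectrum {2, 0.5, 0.5}
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  dec <- qamsfp:::pca_from_cor(R)
  expect_equal(dec$eigenvalues, c(2, 0.5, 0.5), tolerance = 1e-8)

  # random matrices vs an independent power-iteration oracle
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(32), 8, 4)
    res <- pca(X)
    oracle <- power_eigen(cor(X))
    expect_equal(res$eigenvalues, oracle$values, tolerance = 1e-6)
  }
})

test_that("pca validates input and names zero-variance columns", {
  X <- cbind(a = rnorm(5), flat = rep(2, 5))
  expect_error(pca(X), "flat")
  expect_error(pca(matrix(1, 1, 3)), "at least 2")
  expect_s3_class(pca(X, mode = "covariance"), "pca_result")
})

test_that("loadings reconstruct the correlation matrix", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rlnorm(10 * 6), 10, 6)
    res <- pca(X)
    expect_equal(tcrossprod(res$loadings), cor(X), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("a 10 x 29 panel yields exactly 9 components summing to 100 %", {
  sim <- make_batch_panel(default_panel_design(seed = 17), traces = FALSE)
  m <- match_truth(sim)
  res <- pca(m)
  expect_equal(ncol(m$areas), 29L)
  expect_equal(res$n_nonzero, 9L)
  expect_equal(sum(res$eigenvalues), 29, tolerance = 1e-9)
  expect_equal(res$cumulative_pct[9], 100, tolerance = 1e-9)
})

test_that("scree table mirrors the eigenvalues in descending order", {
  set.seed(4)
  res <- pca(matrix(rnorm(40), 8, 5))
  sc <- scree_table(res)
  expect_equal(nrow(sc), 5L)
  expect_equal(sc$eigenvalue, res$eigenvalues)
  expect_true(all(diff(sc$eigenvalue) <= 1e-12))
})

test_that("NIPALS PLS-DA honours its structural identities", {
  set.seed(10)
  # p = 1: single weight +/-1, VIP exactly 1
  X1 <- matrix(rnorm(10), 10, 1)
  m1 <- nipals_plsda(X1, rep(c("A", "B"), 5), n_components = 1)
  expect_equal(abs(m1$weights[1, 1]), 1)
  expect_equal(unname(vip(m1)), 1)

  # duplicated column: symmetric |weights|
  x <- rnorm(12)
  m2 <- nipals_plsda(cbind(x, x + rnorm(12, 0, 1e-9)),
                     rep(c("A", "B"), 6), n_components = 1)
  expect_equal(unname(abs(m2$weights[1, 1])),
               unname(abs(m2$weights[2, 1])), tolerance = 1e-4)

  # reconstruction at full rank: scores %*% t(loadings) == scaled X
  set.seed(11)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- rep(c("A", "B"), 3)
  mf <- nipals_plsda(X, y, n_components = 4)
  expect_equal(mf$x_scores %*% t(mf$x_loadings), scale(X),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sum of squared VIPs equals the number of variables", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(3:12, 1)
    X <- matrix(rnorm(14 * p), 14, p)
    m <- nipals_plsda(X, rep(c("A", "B"), 7),
                      n_components = sample(1:3, 1))
    expect_equal(sum(vip(m)^2), p, tolerance = 1e-9)
  }
})

test_that("VIP matches the hand-computed single-component value", {
  model <- structure(list(weights = matrix(c(0.6, 0.8), 2, 1),
                          ss_y = 1), class = "pls_model")
  expect_equal(unname(vip(model)),
               c(sqrt(2 * 0.36), sqrt(2 * 0.64)), tolerance = 1e-12)
  expect_equal(unname(round(vip(model), 3)), c(0.849, 1.131))
})

test_that("a variable that separates the classes gets the top VIP", {
  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 8), 20, 8)
    X[1:10, 3] <- X[1:10, 3] + 3   # 3 SD effect on variable 3 only
    v <- vip(nipals_plsda(X, rep(c("case", "control"), each = 10),
                          n_components = 2))
    which.max(v) == 3 && v[3] > 1 && sum(v > 1) <= 3
  }, logical(1))
  expect_true(all(hits))
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  X <- matrix(rnorm(10 * 8), 10, 8)
  X[1:5, 3] <- X[1:5, 3] + 3
  y <- rep(c("A", "B"), each = 5)
  ours <- vip(nipals_plsda(X, y, n_components = 2))
  theirs <- mixOmics::vip(mixOmics::plsda(X, factor(y), ncomp = 2))[, 2]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("key-component screening uses a strict threshold and sorts", {
  expect_equal(nrow(screen_key_components(c(a = 0.2, b = 0.9))), 0L)
  one <- screen_key_components(c(a = 0.2, b = 1.4))
  expect_equal(one$peak, "b")
  ordered <- screen_key_components(c(p1 = 1.2, p2 = 0.9, p3 = 1.5))
  expect_equal(ordered$peak, c("p3", "p1"))
  expect_equal(nrow(screen_key_components(c(x = 1.0), threshold = 1)), 0L)
})
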