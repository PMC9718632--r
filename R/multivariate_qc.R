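# Multivariate key-component screening: PCA on the common-peak area
# matrix and NIPALS PLS-DA with variable-importance-in-projection (VIP)
# scores.

as_area_matrix <- function(x) {
  if (inherits(x, "common_peak_matrix")) x$areas else as.matrix(x)
}

pca_from_cor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  contrib <- 100 * lambda / sum(lambda)
  nz <- lambda / sum(lambda) > 1e-10
  list(eigenvalues = lambda, vectors = e$vectors, contribution_pct = contrib,
       cumulative_pct = cumsum(contrib), n_nonzero = sum(nz))
}

#' Principal component analysis of a peak-area matrix
#'
#' Eigendecomposition of the p x p correlation matrix (default) or
#' covariance matrix of a samples x variables area matrix. Loadings are
#' reported as component loadings (eigenvector times the square root of
#' the eigenvalue), the "initial factor load matrix" convention, so in
#' correlation mode they are the correlations between variables and
#' components and lie in [-1, 1]. In correlation mode the eigenvalues sum
#' to p and a component is counted as non-zero when its eigenvalue
#' exceeds 1e-10 relative to the eigenvalue total; with n samples at most
#' min(n - 1, p) components are non-zero.
#'
#' @param x a [common_peak_matrix()] or numeric matrix
#'   (samples x variables).
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return An object of class `pca_result`: `eigenvalues` (descending),
#'   `contribution_pct`, `cumulative_pct`, `loadings`, `scores`,
#'   `n_nonzero`.
#' @export
pca <- function(x, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  X <- as_area_matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || p < 1L) stop_domain("need at least 2 samples and 1 variable")
  sds <- apply(X, 2L, stats::sd)
  if (mode == "correlation") {
    zv <- which(sds == 0)
    if (length(zv))
      stop_domain("zero-variance column(s) in correlation mode: ",
                  paste(colnames(X)[zv] %||% zv, collapse = ", "))
    R <- stats::cor(X)
    Xs <- scale(X, center = TRUE, scale = TRUE)
  } else {
    R <- stats::cov(X)
    Xs <- scale(X, center = TRUE, scale = FALSE)
  }
  dec <- pca_from_cor(R)
  loadings <- dec$vectors %*% diag(sqrt(dec$eigenvalues), p, p)
  scores <- Xs %*% dec$vectors
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(p)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(p)))
  structure(list(eigenvalues = dec$eigenvalues,
                 contribution_pct = dec$contribution_pct,
                 cumulative_pct = dec$cumulative_pct,
                 loadings = loadings, scores = scores,
                 n_nonzero = dec$n_nonzero, mode = mode),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %s mode, %d non-zero components\n",
              x$mode, x$n_nonzero))
  print(utils::head(scree_table(x), x$n_nonzero))
  invisible(x)
}

#' Scree data of a PCA result
#'
#' @param result a [pca()] result.
#' @return Data frame with `component`, `eigenvalue`,
#'   `contribution_pct`, `cumulative_pct` (eigenvalues descending).
#' @export
scree_table <- function(result) {
  stopifnot(inherits(result, "pca_result"))
  data.frame(component = seq_along(result$eigenvalues),
             eigenvalue = result$eigenvalues,
             contribution_pct = result$contribution_pct,
             cumulative_pct = result$cumulative_pct)
}

#' PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis: X is autoscaled
#' (centered, unit variance), the class labels are dummy-coded (one
#' centered indicator column per class, deterministic class order) and
#' components are extracted by the NIPALS algorithm with X deflation.
#' Per component the unit-norm X weight vector, scores and the explained
#' sum of squares of the response are stored for VIP computation.
#'
#' @param X samples x variables matrix (or [common_peak_matrix()]).
#' @param y class labels (>= 2 classes).
#' @param n_components number of latent components (defaults to
#'   `min(n - 1, p, 2)`).
#' @param tol convergence tolerance on the weight-vector change.
#' @param max_iter maximum NIPALS iterations per component.
#' @return An object of class `pls_model`: `weights` (p x A, unit norm),
#'   `x_scores` (n x A), `x_loadings`, `y_loadings`, `ss_y` (per-component
#'   explained response sum of squares), `classes`, `n_components`.
#' @export
nipals_plsda <- function(X, y, n_components = NULL, tol = 1e-12,
                         max_iter = 500L) {
  X <- as_area_matrix(X)
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  if (nlevels(y) < 2L) stop_domain("need at least 2 classes")
  if (length(y) != n) stop_domain("y must have one label per row of X")
  n_components <- n_components %||% max(1L, min(n - 1L, p, 2L))
  if (n_components > min(n - 1L, p))
    stop_domain("n_components must be <= min(n - 1, p)")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop_domain("zero-variance column(s) in X")
  Xd <- scale(X, center = TRUE, scale = TRUE)
  Y <- stats::model.matrix(~ y - 1)
  Yd <- scale(Y, center = TRUE, scale = FALSE)

  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Yd), n_components)
  ss_y <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2L, stats::var))]
    w_old <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
      w_old <- w
    }
    if (!converged)
      stop(errorCondition(
        paste0("NIPALS did not converge for component ", a,
               " after ", max_iter, " iterations"),
        class = c("qamsfp_convergence_error", "qamsfp_error")))
    pl <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pl; Q[, a] <- q
    ss_y[a] <- sum(tt^2) * sum(q^2)
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, q)
  }
  rownames(W) <- colnames(X)
  structure(list(weights = W, x_scores = Tm, x_loadings = P, y_loadings = Q,
                 ss_y = ss_y, classes = levels(y),
                 n_components = n_components),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, classes: %s\n",
              x$n_components, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a(SS_a * w_aj^2) / sum_a(SS_a))` with unit-norm
#' weight vectors, so that `sum(VIP^2) = p` for every fitted model.
#'
#' @param model a [nipals_plsda()] model.
#' @return Named numeric vector of per-variable VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ss <- model$ss_y
  if (sum(ss) == 0) stop_domain("degenerate model: no explained response")
  p <- nrow(model$weights)
  scores <- sqrt(p * as.numeric(model$weights^2 %*% ss) / sum(ss))
  names(scores) <- rownames(model$weights)
  scores
}

#' Screen key components by VIP threshold
#'
#' @param vip_scores named VIP vector (names = peak ids).
#' @param threshold VIP cut-off; peaks strictly above it are key
#'   components.
#' @return Data frame with `peak`, `vip`, sorted descending by VIP.
#' @export
screen_key_components <- function(vip_scores, threshold = 1.0) {
  if (any(!is.finite(vip_scores))) stop_domain("VIP scores must be finite")
  keep <- vip_scores > threshold
  out <- data.frame(peak = names(vip_scores)[keep] %||%
                      as.character(which(keep)),
                    vip = unname(vip_scores[keep]))
  out[order(-out$vip), , drop = FALSE]
}
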