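#' Shared least-squares kernel
#'
#' Pivoted-QR least squares used by every fixed-effects style design.
#' Collinear columns are detected at a relative tolerance of 1e-10 on the
#' QR diagonal, dropped and reported by name. Model-based standard errors
#' use \eqn{\hat\sigma^2 (X'X)^{-1}} with residual degrees of freedom
#' `n - rank - absorbed`; `absorbed` accounts for parameters removed by a
#' prior transformation (e.g. the unit means absorbed by the within
#' transform) so the within and dummy parameterisations report identical
#' standard errors. Cluster-robust standard errors implement the CR1
#' sandwich with small-sample factor
#' \eqn{G/(G-1)\,(n-1)/(n-k)} where `G` is the number of clusters and
#' `k = rank + absorbed`.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix with column names.
#' @param cluster optional vector of cluster labels for CR1 standard
#'   errors.
#' @param se_type `"model"` or `"cluster_robust"`. With a single cluster
#'   the CR1 factor is undefined; the fit falls back to model-based
#'   standard errors with a warning.
#' @param absorbed number of parameters absorbed by a prior
#'   transformation (default 0).
#' @return A list with `coef` (named vector over retained columns), `se`,
#'   `vcov`, `sigma2`, `dof`, `rank`, `n`, `dropped` (names of collinear
#'   columns removed), `fitted`, `residuals`, `se_type`.
#' @export
fit_ols_core <- function(y, X, cluster = NULL,
                         se_type = c("model", "cluster_robust"),
                         absorbed = 0L) {
  se_type <- match.arg(se_type)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop_estimation("design matrix has %d rows for %d responses", nrow(X), n)

  qr_x <- qr(X, tol = 1e-10)
  rank <- qr_x$rank
  if (rank == 0) stop_estimation("design matrix has rank 0")
  keep <- qr_x$pivot[seq_len(rank)]
  dropped <- colnames(X)[qr_x$pivot[-seq_len(rank)]]
  if (length(dropped) > 0) {
    log_msg("dropped %d collinear column(s): %s", length(dropped),
            paste(dropped, collapse = ", "))
  }
  k <- rank + absorbed
  if (n <= k) stop_estimation("not enough observations (n = %d) for %d parameters", n, k)

  Xk <- X[, keep, drop = FALSE]
  qr_k <- qr(Xk)
  beta <- qr.coef(qr_k, y)
  fitted <- drop(Xk %*% beta)
  res <- y - fitted
  dof <- n - k
  sigma2 <- sum(res^2) / dof
  Rinv <- backsolve(qr.R(qr_k), diag(rank))
  xtx_inv <- Rinv %*% t(Rinv)                   # (X'X)^{-1}

  if (se_type == "cluster_robust") {
    if (is.null(cluster)) stop_config("cluster_robust standard errors need cluster labels")
    cl <- as.character(cluster)
    G <- length(unique(cl))
    if (G < 2) {
      warning("only one cluster: falling back to model-based standard errors")
      se_type <- "model"
    } else {
      scores <- rowsum(Xk * res, cl)            # per-cluster score sums
      meat <- crossprod(scores)
      adj <- G / (G - 1) * (n - 1) / (n - k)
      vcov <- adj * xtx_inv %*% meat %*% xtx_inv
    }
  }
  if (se_type == "model") vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(names(beta), names(beta))
  list(coef = beta, se = sqrt(pmax(diag(vcov), 0)), vcov = vcov,
       sigma2 = sigma2, dof = dof, rank = rank, n = n,
       dropped = dropped, fitted = fitted, residuals = res,
       se_type = se_type)
}
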