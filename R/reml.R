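# Restricted maximum likelihood machinery for Gaussian random-intercept
# models, written against the profiled criterion: for variance ratio(s)
# theta = sigma2_group / sigma2, the fixed effects are the GLS solution
# and sigma2 is profiled out, leaving
#   f(theta) = log|V| + log|X' V^-1 X| + (n - p) log(r' V^-1 r)
# (constants dropped), V = I + sum_c theta_c Z_c Z_c'. One ratio is
# profiled by one-dimensional bounded search on the log scale over
# theta in [1e-8, 1e8]; two ratios use a nested profile (outer search
# over the first ratio, inner search over the second).

REML_THETA_RANGE <- c(1e-8, 1e8)

# Single random intercept: closed-form group algebra. For group g with
# n_g rows, V_g^{-1} = I - a_g J with a_g = theta / (1 + n_g theta),
# so the GLS cross-products only need per-group sums.
reml_random_intercept <- function(y, X, group, tol = 1e-10) {
  X <- as.matrix(X)
  g <- as.character(group)
  n <- length(y); p <- ncol(X)
  if (length(unique(g)) < 2) stop_estimation("random intercept needs >= 2 groups")
  Sx <- rowsum(X, g)                            # group sums of columns
  Sy <- drop(rowsum(y, g))
  ng <- drop(rowsum(rep(1, n), g))
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)

  profile <- function(log_theta) {
    theta <- exp(log_theta)
    a <- theta / (1 + ng * theta)
    XVX <- XtX - crossprod(Sx * sqrt(a))
    XVy <- Xty - drop(crossprod(Sx, a * Sy))
    yVy <- yty - sum(a * Sy^2)
    ch <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XVy))
    rss <- max(yVy - sum(beta * XVy), .Machine$double.eps)
    crit <- sum(log1p(ng * theta)) + 2 * sum(log(diag(ch))) + (n - p) * log(rss)
    list(crit = crit, beta = beta, rss = rss, chol_XVX = ch, theta = theta)
  }

  opt <- stats::optimize(function(lt) profile(lt)$crit,
                         interval = log(REML_THETA_RANGE), tol = tol)
  # the criterion can be monotone down to a boundary; check both ends
  ends <- log(REML_THETA_RANGE)
  cands <- c(opt$minimum, ends)
  crits <- vapply(cands, function(lt) profile(lt)$crit, numeric(1))
  best <- profile(cands[which.min(crits)])
  if (!is.finite(best$crit)) {
    stop_estimation("REML criterion non-finite at theta = %g (criterion %g)",
                    best$theta, best$crit)
  }
  sigma2 <- best$rss / (n - p)
  xvx_inv <- chol2inv(best$chol_XVX)
  beta <- drop(best$beta)
  names(beta) <- colnames(X)
  vcov <- sigma2 * xvx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = beta, se = sqrt(pmax(diag(vcov), 0)), vcov = vcov,
       sigma2 = sigma2, sigma2_group = best$theta * sigma2,
       theta = best$theta, dof = n - p, n = n, criterion = best$crit)
}

# Two nested/crossed random intercepts via the Woodbury identity:
# with Z = [Z1 Z2] (q columns total) and D = diag(theta1, ..., theta2, ...),
# V^-1 = I - Z D^{1/2} M^-1 D^{1/2} Z' with M = I_q + D^{1/2} Z'Z D^{1/2},
# and log|V| = log|M|. All cross-products are precomputed once.
reml_two_component <- function(y, X, group1, group2,
                               tol_outer = 1e-9, tol_inner = 1e-10) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  g1 <- factor(as.character(group1)); g2 <- factor(as.character(group2))
  q1 <- nlevels(g1); q2 <- nlevels(g2)
  if (q1 < 2 || q2 < 2) stop_estimation("each random term needs >= 2 levels")
  Z1 <- stats::model.matrix(~ 0 + g1); Z2 <- stats::model.matrix(~ 0 + g2)
  Z <- cbind(Z1, Z2)
  ZtZ <- crossprod(Z); ZtX <- crossprod(Z, X); Zty <- drop(crossprod(Z, y))
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)

  eval_theta <- function(theta1, theta2) {
    dhalf <- sqrt(c(rep(theta1, q1), rep(theta2, q2)))
    M <- diag(q1 + q2) + (dhalf %o% dhalf) * ZtZ
    chM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(chM)) return(list(crit = Inf))
    # W = M^-1 applied to D^{1/2} Z' {X, y}
    UX <- dhalf * ZtX; Uy <- dhalf * Zty
    WX <- backsolve(chM, forwardsolve(t(chM), UX))
    Wy <- backsolve(chM, forwardsolve(t(chM), Uy))
    XVX <- XtX - crossprod(UX, WX)
    XVy <- Xty - drop(crossprod(UX, Wy))
    yVy <- yty - sum(Uy * Wy)
    ch <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XVy))
    rss <- max(yVy - sum(beta * XVy), .Machine$double.eps)
    crit <- 2 * sum(log(diag(chM))) + 2 * sum(log(diag(ch))) +
      (n - p) * log(rss)
    list(crit = crit, beta = beta, rss = rss, chol_XVX = ch)
  }

  lrange <- log(REML_THETA_RANGE)
  inner <- function(lt1) {
    o <- stats::optimize(function(lt2) eval_theta(exp(lt1), exp(lt2))$crit,
                         interval = lrange, tol = tol_inner)
    o
  }
  outer_opt <- stats::optimize(function(lt1) inner(lt1)$objective,
                               interval = lrange, tol = tol_outer)
  lt1 <- outer_opt$minimum
  lt2 <- inner(lt1)$minimum
  # guard the boundaries of the outer ratio as well
  for (cand in lrange) {
    alt <- inner(cand)
    if (alt$objective < eval_theta(exp(lt1), exp(lt2))$crit) {
      lt1 <- cand; lt2 <- alt$minimum
    }
  }
  theta1 <- exp(lt1); theta2 <- exp(lt2)
  best <- eval_theta(theta1, theta2)
  if (!is.finite(best$crit)) stop_estimation("two-component REML failed to converge")
  sigma2 <- best$rss / (n - p)
  beta <- drop(best$beta); names(beta) <- colnames(X)
  vcov <- sigma2 * chol2inv(best$chol_XVX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = beta, se = sqrt(pmax(diag(vcov), 0)), vcov = vcov,
       sigma2 = sigma2, sigma2_group1 = theta1 * sigma2,
       sigma2_group2 = theta2 * sigma2,
       theta = c(theta1, theta2), dof = n - p, n = n, criterion = best$crit)
}
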