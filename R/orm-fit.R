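# Proportional-odds (cumulative logit) model fitted by Newton-Raphson.
#
# The number of ordinal categories equals the number of distinct response
# values, which for relative abundances is close to the sample size. General
# ordinal-regression fitters that optimize all thresholds with quasi-Newton
# methods scale poorly in that regime; here the full Newton step is cheap
# because gradient and Hessian are accumulated in vectorized form (the
# threshold block of the Hessian is tridiagonal) and the per-fit parameter
# count stays in the low hundreds.
#
# Parameterization: P(Y <= j | x) = plogis(zeta_j - x'beta), so positive
# beta means higher response categories (larger abundance) in that group.

orm_fit <- function(y, X, max_iter = 50L, tol = 1e-8) {
  n <- length(y)
  lev <- sort(unique(y))
  k <- length(lev)
  if (k < 2L) {
    return(list(degenerate = TRUE, k = k))
  }
  cc <- match(y, lev)                       # category index 1..k, ties share
  X <- as.matrix(X)
  p <- ncol(X)

  counts <- tabulate(cc, nbins = k)
  zeta <- stats::qlogis(cumsum(counts[-k]) / n)
  beta <- rep(0, p)
  theta <- c(zeta, beta)

  has_u <- cc < k                           # upper threshold exists
  has_l <- cc > 1L                          # lower threshold exists
  iu <- cc                                  # zeta index of upper threshold
  il <- cc - 1L                             # zeta index of lower threshold
  both <- has_u & has_l

  loglik <- function(theta) {
    zeta <- theta[seq_len(k - 1L)]
    eta <- drop(X %*% theta[k:(k - 1L + p)])
    A <- rep(1, n); A[has_u] <- stats::plogis(zeta[iu[has_u]] - eta[has_u])
    B <- rep(0, n); B[has_l] <- stats::plogis(zeta[il[has_l]] - eta[has_l])
    pr <- A - B
    if (any(pr <= 0)) return(-Inf)
    sum(log(pr))
  }

  score_hessian <- function(theta) {
    zeta <- theta[seq_len(k - 1L)]
    eta <- drop(X %*% theta[k:(k - 1L + p)])
    A <- rep(1, n); fA <- gA <- rep(0, n)
    A[has_u] <- stats::plogis(zeta[iu[has_u]] - eta[has_u])
    fA[has_u] <- A[has_u] * (1 - A[has_u])
    gA[has_u] <- fA[has_u] * (1 - 2 * A[has_u])
    B <- rep(0, n); fB <- gB <- rep(0, n)
    B[has_l] <- stats::plogis(zeta[il[has_l]] - eta[has_l])
    fB[has_l] <- B[has_l] * (1 - B[has_l])
    gB[has_l] <- fB[has_l] * (1 - 2 * B[has_l])
    pr <- pmax(A - B, 1e-300)

    ru <- fA / pr; rl <- fB / pr; rd <- ru - rl
    npar <- k - 1L + p
    grad <- numeric(npar)
    H <- matrix(0, npar, npar)

    acc <- function(vals, idx) {          # sum vals by integer index 1..k-1
      out <- numeric(k - 1L)
      s <- rowsum(vals, idx)
      out[as.integer(rownames(s))] <- s
      out
    }

    grad[seq_len(k - 1L)] <- acc(ru[has_u], iu[has_u]) - acc(rl[has_l], il[has_l])
    grad[k:(k - 1L + p)] <- drop(crossprod(X, -rd))

    # zeta-zeta block: tridiagonal
    dz <- acc((gA / pr - ru^2)[has_u], iu[has_u]) +
          acc((-gB / pr - rl^2)[has_l], il[has_l])
    diag(H)[seq_len(k - 1L)] <- dz
    if (any(both)) {
      od <- acc((fA * fB / pr^2)[both], il[both])  # couples zeta_{c-1}, zeta_c
      for (j in which(od != 0)) {
        H[j, j + 1L] <- H[j, j + 1L] + od[j]
        H[j + 1L, j] <- H[j + 1L, j] + od[j]
      }
    }

    # zeta-beta cross terms
    hue <- -gA / pr + fA * rd / pr        # d2/d zeta_c d eta
    hle <- gB / pr - fB * rd / pr         # d2/d zeta_{c-1} d eta
    for (j in seq_len(p)) {
      cross <- acc((hue * X[, j])[has_u], iu[has_u]) +
               acc((hle * X[, j])[has_l], il[has_l])
      H[seq_len(k - 1L), k - 1L + j] <- cross
      H[k - 1L + j, seq_len(k - 1L)] <- cross
    }

    # beta-beta block
    hee <- (gA - gB) / pr - rd^2
    H[k:(k - 1L + p), k:(k - 1L + p)] <- crossprod(X, X * hee)
    list(grad = grad, H = H)
  }

  ll <- loglik(theta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sh <- score_hessian(theta)
    step <- tryCatch(solve(sh$H, sh$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_theta <- theta - step
    new_ll <- loglik(new_theta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll ||
            is.unsorted(new_theta[seq_len(k - 1L)], strictly = TRUE)) &&
           halvings < 30L) {
      step <- step / 2
      new_theta <- theta - step
      new_ll <- loglik(new_theta)
      halvings <- halvings + 1L
    }
    if (!is.finite(new_ll) || new_ll < ll) break
    improved <- new_ll - ll
    theta <- new_theta
    ll <- new_ll
    if (improved < tol * (abs(ll) + tol)) {
      converged <- TRUE
      break
    }
  }

  sh <- score_hessian(theta)
  vcov_beta <- tryCatch({
    v <- solve(-sh$H)
    v[k:(k - 1L + p), k:(k - 1L + p), drop = FALSE]
  }, error = function(e) matrix(NA_real_, p, p))

  list(degenerate = FALSE, k = k,
       zeta = theta[seq_len(k - 1L)],
       beta = theta[k:(k - 1L + p)],
       vcov_beta = vcov_beta,
       loglik = ll,
       converged = converged || max(abs(sh$grad)) < 1e-3)
}
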