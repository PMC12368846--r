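# Fast per-site random-intercept solver.
#
# Model per site: y = X b + Z u + e, u ~ N(0, su2 I_G) an intercept per
# individual, e ~ N(0, se2 I_N). Writing lambda = su2 / se2, the covariance
# is V = se2 (I + lambda Z Z'). Z Z' is block diagonal over clusters, so its
# eigenbasis is known: within each cluster of size m_g, the normalized mean
# vector carries eigenvalue m_g and its orthogonal complement eigenvalue 0.
# Rotating y and X into that basis (once per design, reused for every site)
# diagonalizes V, and the REML criterion profiles down to a 1-D function of
# lambda whose site-dependent part is only (N - p) * log(RSS_w(lambda)).
# That lets the criterion be evaluated for all sites simultaneously on a
# grid of lambda values with a handful of matrix products.

cluster_rotation <- function(cluster) {
  cluster <- factor(cluster)
  N <- length(cluster)
  Q <- matrix(0, N, N)
  Lam <- numeric(N)
  col <- 1L
  for (g in levels(cluster)) {
    idx <- which(cluster == g)
    m <- length(idx)
    Qg <- qr.Q(qr(matrix(1, m, 1)), complete = TRUE)
    if (Qg[1, 1] < 0) Qg[, 1] <- -Qg[, 1]
    Q[idx, col:(col + m - 1L)] <- Qg
    Lam[col] <- m
    col <- col + m
  }
  list(Q = Q, Lam = Lam)
}

# Evaluate, for every site at once, the profiled (RE)ML pieces at one lambda.
# Xt, Yt are rotated; Xm/Ym/yy2 restrict to the rows with Lam > 0 (only
# those rows' weights depend on lambda).
mer_profile_eval <- function(lambda, env) {
  d <- lambda * env$Lm / (1 + lambda * env$Lm)
  XtWX <- env$XtX0 - crossprod(env$Xm, env$Xm * d)
  XtWY <- env$XtY0 - crossprod(env$Xm * d, env$Ym)
  Bc <- solve(XtWX, XtWY)
  RSS <- pmax(env$yy0 - colSums(env$Ym^2 * d) - colSums(Bc * XtWY),
              .Machine$double.xmin)
  logdet_v <- sum(log1p(lambda * env$Lm))
  logdet_x <- determinant(XtWX, logarithm = TRUE)$modulus
  const <- if (env$reml) logdet_v + as.numeric(logdet_x) else logdet_v
  nfac <- if (env$reml) env$N - env$p else env$N
  list(crit = nfac * log(RSS) + const, RSS = RSS, XtWX = XtWX, B = Bc)
}

fit_mer_sites <- function(X, Y, cluster, reml = TRUE,
                          refine = "quadratic",
                          lambda_grid = exp(seq(log(1e-4), log(1e3),
                                                length.out = 43))) {
  rot <- cluster_rotation(cluster)
  Xt <- crossprod(rot$Q, X)
  Yt <- crossprod(rot$Q, Y)
  top <- rot$Lam > 0
  env <- list2env(list(
    N = nrow(X), p = ncol(X), reml = reml,
    XtX0 = crossprod(Xt), XtY0 = crossprod(Xt, Yt),
    yy0 = colSums(Yt^2),
    Xm = Xt[top, , drop = FALSE], Ym = Yt[top, , drop = FALSE],
    Lm = rot$Lam[top]))

  grid <- c(0, lambda_grid)
  crit <- matrix(NA_real_, length(grid), ncol(Y))
  for (k in seq_along(grid))
    crit[k, ] <- mer_profile_eval(grid[k], env)$crit
  best <- max.col(-t(crit))  # per-site argmin over the grid
  lambda_hat <- grid[best]

  if (refine == "quadratic") {
    interior <- which(best > 2 & best < length(grid))
    if (length(interior)) {
      k <- best[interior]
      lx <- log(grid)
      x0 <- lx[k - 1]; x1 <- lx[k]; x2 <- lx[k + 1]
      y0 <- crit[cbind(k - 1, interior)]
      y1 <- crit[cbind(k, interior)]
      y2 <- crit[cbind(k + 1, interior)]
      denom <- (y0 - y1) * (x1 - x2) - (y1 - y2) * (x0 - x1)
      xs <- 0.5 * ((y0 - y1) * (x1^2 - x2^2) - (y1 - y2) * (x0^2 - x1^2)) /
        ifelse(abs(denom) < 1e-300, NA, denom)
      ok <- is.finite(xs) & xs > x0 & xs < x2
      lambda_hat[interior[ok]] <- exp(xs[ok])
    }
  } else if (refine == "brent") {
    lx <- log(lambda_grid)
    for (s in seq_len(ncol(Y))) {
      k <- best[s]
      if (k == 1) {  # boundary at lambda = 0: search the first interval
        lo <- log(lambda_grid[1] / 10); hi <- lx[1]
      } else {
        kk <- k - 1L  # index into lambda_grid
        lo <- if (kk > 1) lx[kk - 1] else log(lambda_grid[1] / 10)
        hi <- if (kk < length(lx)) lx[kk + 1] else lx[length(lx)]
      }
      f <- function(loglam) mer_site_crit(exp(loglam), s, env)
      opt <- optimize(f, c(lo, hi), tol = 1e-6)
      if (opt$objective < crit[k, s]) lambda_hat[s] <- exp(opt$minimum)
    }
  }
  list(lambda = lambda_hat, env = env)
}

mer_site_crit <- function(lambda, s, env) {
  d <- lambda * env$Lm / (1 + lambda * env$Lm)
  XtWX <- env$XtX0 - crossprod(env$Xm, env$Xm * d)
  XtWY <- env$XtY0[, s] - crossprod(env$Xm * d, env$Ym[, s])
  Bc <- solve(XtWX, XtWY)
  RSS <- max(env$yy0[s] - sum(d * env$Ym[, s]^2) - sum(Bc * XtWY),
             .Machine$double.xmin)
  logdet_v <- sum(log1p(lambda * env$Lm))
  const <- if (env$reml)
    logdet_v + as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  else logdet_v
  nfac <- if (env$reml) env$N - env$p else env$N
  nfac * log(RSS) + const
}

# final GLS fit per site at its estimated lambda; returns coefficient
# estimates, selected covariance entries and variance components
mer_finalize <- function(lambda_hat, env, sel) {
  S <- length(lambda_hat)
  p <- env$p
  m <- length(sel)
  est <- matrix(NA_real_, m, S)
  vcv <- list()
  for (i in seq_len(m)) for (j in i:m) vcv[[paste0(i, j)]] <- numeric(S)
  sigma_e2 <- sigma_u2 <- numeric(S)
  quad_int <- numeric(S)
  intsel <- seq.int(2L, m)  # interactions within the selection
  dffac <- if (env$reml) env$N - p else env$N
  # group sites sharing a lambda value (grid hits) to reuse factorizations
  fac_cache <- new.env()
  for (s in seq_len(S)) {
    lam <- lambda_hat[s]
    key <- sprintf("%.12g", lam)
    fc <- fac_cache[[key]]
    if (is.null(fc)) {
      d <- lam * env$Lm / (1 + lam * env$Lm)
      XtWX <- env$XtX0 - crossprod(env$Xm, env$Xm * d)
      Ci <- chol2inv(chol(XtWX))
      fc <- list(d = d, Ci = Ci)
      fac_cache[[key]] <- fc
    }
    XtWY <- env$XtY0[, s] - crossprod(env$Xm * fc$d, env$Ym[, s])
    b <- drop(fc$Ci %*% XtWY)
    RSS <- max(env$yy0[s] - sum(fc$d * env$Ym[, s]^2) - sum(b * XtWY),
               .Machine$double.xmin)
    s2 <- RSS / dffac
    est[, s] <- b[sel]
    for (i in seq_len(m)) for (j in i:m)
      vcv[[paste0(i, j)]][s] <- s2 * fc$Ci[sel[i], sel[j]]
    # joint Wald over interaction terms
    Vint <- s2 * fc$Ci[sel[intsel], sel[intsel], drop = FALSE]
    bi <- b[sel[intsel]]
    quad_int[s] <- drop(crossprod(bi, solve(Vint, bi)))
    sigma_e2[s] <- s2
    sigma_u2[s] <- lam * s2
  }
  names(vcv)[1] <- "11"
  list(est = est, vcv = vcv, quad_int = quad_int,
       sigma_e2 = sigma_e2, sigma_u2 = sigma_u2)
}

fit_mer_impl <- function(beta, sheet, reference, reml = TRUE,
                         refine = "quadratic") {
  cluster <- factor(sheet$individual_id)
  X <- build_design(sheet, with_celltype = TRUE, reference = reference)
  info <- pooled_term_index(X, sheet, reference)
  Y <- t(beta)
  ok <- colVars_fast(Y) > .Machine$double.eps
  prof <- fit_mer_sites(X, Y, cluster, reml = reml, refine = refine)
  fin <- mer_finalize(prof$lambda, prof$env, info$sel)
  m <- length(info$sel)
  se <- do.call(rbind, lapply(seq_len(m), function(i)
    sqrt(fin$vcv[[paste0(i, i)]])))
  stat <- fin$est / se
  p <- 2 * pnorm(-abs(stat))
  q <- m - 1
  joint_stat <- fin$quad_int
  joint_p <- pchisq(joint_stat, df = q, lower.tail = FALSE)
  eff <- celltype_effects(info, fin$est, fin$vcv,
                          function(z) 2 * pnorm(-abs(z)))
  out <- pooled_results(rownames(beta), info, fin$est, se, stat, p,
                        joint_stat, joint_p, eff,
                        ok & is.finite(fin$sigma_e2) & fin$sigma_e2 > 0)
  out$sigma_u2 <- fin$sigma_u2
  out$sigma_e2 <- fin$sigma_e2
  out
}
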