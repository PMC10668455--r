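#' Fixed- and random-effects design rows for the density model
#'
#' The density outcome (BI-RADS treated as a continuous value 1--4) is
#' modelled with fixed effects for intercept, a quartic polynomial in
#' centred age (in 5-year units), BMI, and an age-by-BMI interaction
#' (linear age term only); the random part is a per-woman intercept and
#' age slope. `a = age/5 - centering`, so `centering = 10` centres at
#' age 50, which conditions the quartic.
#'
#' @param age age in years (vectorised)
#' @param bmi BMI in kg/m² (already winsorized/imputed; vectorised)
#' @param centering centering constant in 5-year units (default 10)
#' @return list with `x` (n x 7 fixed-effects matrix: 1, a, a², a³, a⁴,
#'   bmi, a·bmi) and `z` (n x 2 random-effects matrix: 1, a)
#' @export
build_design <- function(age, bmi, centering = 10) {
  a <- age / 5 - centering
  x <- cbind(1, a, a^2, a^3, a^4, bmi, a * bmi)
  colnames(x) <- c("intercept", "a", "a2", "a3", "a4", "bmi", "a_bmi")
  z <- cbind(1, a)
  colnames(z) <- c("b0", "b1")
  list(x = x, z = z)
}

#' Linear mixed model parameters
#'
#' @param beta length-7 fixed-effect vector (density units)
#' @param G 2x2 symmetric positive-semidefinite random-effects covariance
#' @param sigma2 residual variance (> 0)
#' @param centering age centering constant in 5-yr units
#' @return object of class `"lmm_params"`
#' @export
lmm_params <- function(beta, G, sigma2, centering = 10) {
  beta <- as.numeric(beta)
  G <- matrix(as.numeric(G), 2, 2)
  stopifnot(length(beta) == 7, sigma2 > 0)
  if (max(abs(G - t(G))) > 1e-8) stop("G must be symmetric")
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("G must be positive semidefinite")
  structure(list(beta = beta, G = (G + t(G)) / 2, sigma2 = sigma2,
                 centering = centering), class = "lmm_params")
}

# Per-woman sufficient statistics for the marginal likelihood.
# Everything the likelihood needs is captured by S_zz, S_zx, S_zy (random
# part) and S_xx, S_xy, S_yy, n per woman, so each likelihood evaluation is
# O(n_women) with small constants.
lmm_suffstats <- function(cohort, centering) {
  s <- cohort$screens
  if (anyNA(s$bmi) || anyNA(s$birads))
    stop("cohort must be preprocessed: no missing bmi/birads")
  d <- build_design(s$age, s$bmi, centering)
  id <- factor(s$woman_id, levels = unique(s$woman_id))
  X <- d$x
  y <- as.numeric(s$birads)
  a <- d$z[, 2]
  m <- nlevels(id)
  # S_zz per woman: (n_i, sum a, sum a^2)
  szz <- cbind(n = as.vector(rowsum(rep(1, length(y)), id)),
               sa = as.vector(rowsum(a, id)),
               sa2 = as.vector(rowsum(a^2, id)))
  szx1 <- rowsum(X, id)                 # row 1 of Z'X per woman (m x 7)
  szx2 <- rowsum(X * a, id)             # row 2
  szy <- cbind(rowsum(y, id), rowsum(y * a, id))
  # stacked 7x7 cross-products via crossprod of the full matrices
  list(m = m, ids = levels(id), n_obs = length(y),
       szz = szz, szx1 = szx1, szx2 = szx2, szy = szy,
       Sxx = crossprod(X), Sxy = crossprod(X, y), Syy = sum(y * y),
       X = X, y = y, id = id, a = a)
}

# Profiled marginal log-likelihood pieces at variance parameters
# theta = (l11, l21, l22, log sigma2), G = LL'.
# Uses V^-1 = s2^-1 I - s2^-2 Z L K^-1 L' Z', K = I + s2^-1 L' Z'Z L,
# log|V| = n log s2 + log|K|; all 2x2 algebra vectorised across women.
lmm_profile <- function(theta, ss, beta_fixed = NULL) {
  L <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
  s2 <- exp(theta[4])
  # C = L' S_zz L per woman, from szz = (n, sa, sa2)
  n_i <- ss$szz[, 1]; sa <- ss$szz[, 2]; sa2 <- ss$szz[, 3]
  # S_zz = [[n, sa], [sa, sa2]]
  # L'SzzL entries (L lower-triangular: [l11 0; l21 l22])
  l11 <- L[1, 1]; l21 <- L[2, 1]; l22 <- L[2, 2]
  # t(L) %*% Szz %*% L
  c11 <- l11^2 * n_i + 2 * l11 * l21 * sa + l21^2 * sa2
  c12 <- l11 * l22 * sa + l21 * l22 * sa2
  c22 <- l22^2 * sa2
  # K = I + C/s2 ; closed-form 2x2 inverse
  k11 <- 1 + c11 / s2; k12 <- c12 / s2; k22 <- 1 + c22 / s2
  detK <- k11 * k22 - k12 * k12
  i11 <- k22 / detK; i12 <- -k12 / detK; i22 <- k11 / detK
  # U_i = L' S_zx (2 x 7) per woman; rows from szx1, szx2
  u1 <- l11 * ss$szx1 + l21 * ss$szx2     # m x 7
  u2 <- l22 * ss$szx2
  v1 <- l11 * ss$szy[, 1] + l21 * ss$szy[, 2]   # L' S_zy, m x 1 each
  v2 <- l22 * ss$szy[, 2]
  # K^-1 U and K^-1 v
  ku1 <- i11 * u1 + i12 * u2
  ku2 <- i12 * u1 + i22 * u2
  kv1 <- i11 * v1 + i12 * v2
  kv2 <- i12 * v1 + i22 * v2
  # A = sum X'V^-1 X = (Sxx - sum U' K^-1 U / s2) / s2
  UKU <- crossprod(u1, ku1) + crossprod(u2, ku2)
  A <- (ss$Sxx - UKU / s2) / s2
  b <- (ss$Sxy - (crossprod(u1, kv1) + crossprod(u2, kv2)) / s2) / s2
  cq <- (ss$Syy - sum(v1 * kv1 + v2 * kv2) / s2) / s2   # sum y'V^-1 y
  logdet <- sum(n_i) * log(s2) + sum(log(detK))
  if (!is.null(beta_fixed)) {
    quad <- cq - 2 * sum(b * beta_fixed) +
      sum(beta_fixed * (A %*% beta_fixed))
    ll <- -0.5 * (ss$n_obs * log(2 * pi) + logdet + quad)
    return(list(loglik = as.numeric(ll), beta = beta_fixed, A = A,
                L = L, sigma2 = s2))
  }
  beta <- solve(A, b)
  quad <- cq - sum(b * beta)              # residual quadratic form at GLS beta
  ll <- -0.5 * (ss$n_obs * log(2 * pi) + logdet + quad)
  list(loglik = as.numeric(ll), beta = as.numeric(beta), A = A,
       L = L, sigma2 = s2)
}

# analytic gradient of the profiled marginal log-likelihood wrt
# theta = (l11, l21, l22, log sigma2); beta-hat dependence drops out by the
# envelope theorem (the beta-score is zero at the GLS solution)
lmm_profile_grad <- function(theta, ss) {
  pr <- lmm_profile(theta, ss)
  L <- pr$L; s2 <- pr$sigma2
  l11 <- L[1, 1]; l21 <- L[2, 1]; l22 <- L[2, 2]
  n_i <- ss$szz[, 1]; sa <- ss$szz[, 2]; sa2 <- ss$szz[, 3]
  c11 <- l11^2 * n_i + 2 * l11 * l21 * sa + l21^2 * sa2
  c12 <- l11 * l22 * sa + l21 * l22 * sa2
  c22 <- l22^2 * sa2
  k11 <- 1 + c11 / s2; k12 <- c12 / s2; k22 <- 1 + c22 / s2
  detK <- k11 * k22 - k12 * k12
  i11 <- k22 / detK; i12 <- -k12 / detK; i22 <- k11 / detK
  e <- ss$y - as.numeric(ss$X %*% pr$beta)
  ze1 <- as.vector(rowsum(e, ss$id))
  ze2 <- as.vector(rowsum(ss$a * e, ss$id))
  se2 <- as.vector(rowsum(e * e, ss$id))
  w1 <- l11 * ze1 + l21 * ze2; w2 <- l22 * ze2
  q1 <- i11 * w1 + i12 * w2; q2 <- i12 * w1 + i22 * w2
  g1 <- l11 * q1; g2 <- l21 * q1 + l22 * q2          # L q
  u1 <- (ze1 - (n_i * g1 + sa * g2) / s2) / s2       # Z'V^-1 e
  u2 <- (ze2 - (sa * g1 + sa2 * g2) / s2) / s2
  t1 <- l11 * u1 + l21 * u2; t2 <- l22 * u2          # L'u
  # M = L K^-1 L'; W = Z'V^-1 Z = (Szz - Szz M Szz / s2)/s2
  M11 <- l11^2 * i11
  M12 <- l11 * (i11 * l21 + i12 * l22)
  M22 <- l21 * (l21 * i11 + l22 * i12) + l22 * (l21 * i12 + l22 * i22)
  P11 <- n_i * M11 + sa * M12; P12 <- n_i * M12 + sa * M22
  P21 <- sa * M11 + sa2 * M12; P22 <- sa * M12 + sa2 * M22
  Q11 <- P11 * n_i + P12 * sa
  Q12 <- P11 * sa + P12 * sa2
  Q22 <- P21 * sa + P22 * sa2
  W11 <- (n_i - Q11 / s2) / s2
  W12 <- (sa - Q12 / s2) / s2
  W22 <- (sa2 - Q22 / s2) / s2
  WL11 <- W11 * l11 + W12 * l21
  WL21 <- W12 * l11 + W22 * l21
  WL22 <- W22 * l22
  trV <- (n_i - (M11 * n_i + 2 * M12 * sa + M22 * sa2) / s2) / s2
  rV2r <- (se2 - 2 * (w1 * q1 + w2 * q2) / s2 +
             (c11 * q1^2 + 2 * c12 * q1 * q2 + c22 * q2^2) / s2^2) / s2^2
  grad <- c(sum(u1 * t1 - WL11),
            sum(u2 * t1 - WL21),
            sum(u2 * t2 - WL22),
            -0.5 * s2 * (sum(trV) - sum(rV2r)))
  list(loglik = pr$loglik, grad = grad)
}

#' Marginal log-likelihood of the density mixed model
#'
#' Sum over women of the multivariate-normal log density of her readings
#' with mean \eqn{X_i \beta} and covariance
#' \eqn{V_i = Z_i G Z_i' + \sigma^2 I}.
#'
#' @param params an [lmm_params()] object
#' @param cohort preprocessed `"cohort"` (no missing bmi/birads)
#' @param centering overrides `params$centering` if given
#' @return scalar log-likelihood
#' @export
lmm_marginal_loglik <- function(params, cohort, centering = params$centering) {
  ss <- lmm_suffstats(cohort, centering)
  ch <- chol_psd(params$G)
  theta <- c(ch[1, 1], ch[2, 1], ch[2, 2], log(params$sigma2))
  lmm_profile(theta, ss, beta_fixed = params$beta)$loglik
}

# lower-triangular Cholesky-like factor of a PSD 2x2 (handles singular G)
chol_psd <- function(G) {
  l11 <- sqrt(max(G[1, 1], 0))
  l21 <- if (l11 > 0) G[2, 1] / l11 else 0
  l22 <- sqrt(max(G[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

#' Fit the density linear mixed model by maximum likelihood
#'
#' Maximises the marginal likelihood over \eqn{(\beta, G, \sigma^2)}.
#' \eqn{\beta} is profiled out by generalised least squares at every
#' variance-component candidate; G is parameterised through its Cholesky
#' factor so positive-semidefiniteness is automatic; the remaining
#' four-dimensional surface is maximised by BFGS with an analytic gradient,
#' then polished by damped Newton steps until the gradient is ~1e-10 (which
#' makes fitted values reproducible across centering constants).
#'
#' @param cohort preprocessed `"cohort"` (no missing bmi/birads, >= 2 women)
#' @param centering age centering constant, 5-yr units (default 10)
#' @param reltol relative log-likelihood convergence tolerance
#' @param maxit iteration cap per optimizer stage
#' @return object of class `"lmm_fit"`: `params` ([lmm_params()]),
#'   `loglik`, `n_women`, `n_obs`, `converged`, `G_identified`
#' @export
fit_lmm_ml <- function(cohort, centering = 10, reltol = 1e-12,
                       maxit = 500) {
  ss <- lmm_suffstats(cohort, centering)
  if (ss$m < 2) stop("need at least 2 women to fit the mixed model")
  G_identified <- any(ss$szz[, 1] >= 2)
  # starting values: OLS residual variance split between G[1,1] and sigma2
  beta0 <- solve(ss$Sxx, ss$Sxy)
  rss <- ss$Syy - sum(ss$Sxy * beta0)
  v0 <- max(rss / ss$n_obs, 1e-6)
  theta0 <- c(sqrt(v0 / 2), 0, sqrt(v0 / 20), log(v0 / 2))
  negll <- function(th) {
    v <- tryCatch(suppressWarnings(-lmm_profile(th, ss)$loglik),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(th) {
    g <- tryCatch(suppressWarnings(-lmm_profile_grad(th, ss)$grad),
                  error = function(e) rep(0, 4))
    g[!is.finite(g)] <- 0
    g
  }
  o1 <- stats::optim(theta0, negll, neggr, method = "BFGS",
                     control = list(maxit = maxit, reltol = reltol))
  par <- o1$par
  conv <- o1$convergence == 0
  # Newton polish on the 4-parameter profile surface: drives the gradient
  # to ~1e-10 so fitted values are reproducible across parameterizations
  for (it in 1:25) {
    g <- neggr(par)
    if (max(abs(g)) < 1e-10) break
    H <- tryCatch(stats::optimHess(par, negll, neggr),
                  error = function(e) NULL)
    step <- if (!is.null(H))
      tryCatch(-solve(H, g), error = function(e) -g)
    else -g
    lam <- 1; v0 <- negll(par)
    repeat {
      cand <- par + lam * step
      if (negll(cand) <= v0 + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- par; break }
    }
    if (identical(cand, par)) break
    par <- cand
  }
  pr <- lmm_profile(par, ss)
  G <- pr$L %*% t(pr$L)
  params <- lmm_params(pr$beta, G, pr$sigma2, centering)
  structure(list(params = params, loglik = pr$loglik,
                 n_women = ss$m, n_obs = ss$n_obs,
                 converged = conv, G_identified = G_identified),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model for BI-RADS density (ML)\n")
  cat(sprintf("  %d women, %d screens, log-likelihood %.3f\n",
              x$n_women, x$n_obs, x$loglik))
  cat("  beta:", paste(sprintf("%.4f", x$params$beta), collapse = " "), "\n")
  cat(sprintf("  G: [%.4f %.4f; %.4f %.4f], sigma2 = %.4f\n",
              x$params$G[1, 1], x$params$G[1, 2], x$params$G[2, 1],
              x$params$G[2, 2], x$params$sigma2))
  if (!x$G_identified)
    cat("  note: all women single-screen; G is not identified\n")
  invisible(x)
}

#' Cluster-robust sandwich covariance for the fixed effects
#'
#' Returns \eqn{A^{-1} B A^{-1}} where A is the observed information and B
#' the sum over women of outer products of per-woman score vectors, both
#' evaluated at the estimates. `scope = "beta"` (default) uses the exact
#' closed-form information \eqn{\sum_i X_i' V_i^{-1} X_i} and scores
#' \eqn{X_i' V_i^{-1} r_i} for the 7 fixed effects; `scope = "full"` extends
#' to all 11 parameters (beta, the three Cholesky parameters of G, log
#' sigma2) by numerical differentiation of the per-woman log-likelihoods.
#'
#' @param fit an `"lmm_fit"`
#' @param cohort the cohort the fit used
#' @param scope `"beta"` or `"full"`
#' @return symmetric PSD covariance matrix (7x7 or 11x11)
#' @export
robust_sandwich_cov <- function(fit, cohort, scope = c("beta", "full")) {
  scope <- match.arg(scope)
  p <- fit$params
  ss <- lmm_suffstats(cohort, p$centering)
  if (scope == "beta") {
    sc <- lmm_beta_scores(p, ss)          # m x 7 per-woman scores + A
    B <- crossprod(sc$scores)
    Ainv <- solve(sc$A)
    V <- Ainv %*% B %*% Ainv
    return((V + t(V)) / 2)
  }
  ch <- chol_psd(p$G)
  th0 <- c(p$beta, ch[1, 1], ch[2, 1], ch[2, 2], log(p$sigma2))
  perwoman <- function(th) lmm_perwoman_loglik(th, ss)
  eps <- 1e-5
  np <- length(th0)
  scores <- matrix(0, ss$m, np)
  for (j in seq_len(np)) {
    e <- th0; e[j] <- e[j] + eps
    f <- th0; f[j] <- f[j] - eps
    scores[, j] <- (perwoman(e) - perwoman(f)) / (2 * eps)
  }
  total <- function(th) sum(lmm_perwoman_loglik(th, ss))
  H <- stats::optimHess(th0, total)
  A <- -(H + t(H)) / 2
  B <- crossprod(scores)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  (V + t(V)) / 2
}

# per-woman beta-scores X_i'V_i^-1 r_i and information sum, closed form
lmm_beta_scores <- function(params, ss) {
  ch <- chol_psd(params$G)
  theta <- c(ch[1, 1], ch[2, 1], ch[2, 2], log(params$sigma2))
  m <- ss$m
  scores <- matrix(0, m, 7)
  A <- matrix(0, 7, 7)
  idx <- split(seq_along(ss$y), ss$id)
  for (w in seq_len(m)) {
    i <- idx[[w]]
    Xi <- ss$X[i, , drop = FALSE]
    Zi <- cbind(1, ss$a[i])
    Vi <- Zi %*% params$G %*% t(Zi) + params$sigma2 * diag(length(i))
    ViX <- solve(Vi, Xi)
    ri <- ss$y[i] - Xi %*% params$beta
    scores[w, ] <- crossprod(ViX, ri)
    A <- A + crossprod(Xi, ViX)
  }
  list(scores = scores, A = A)
}

# vector of per-woman marginal log-likelihood contributions at
# th = (beta[7], l11, l21, l22, log sigma2)
lmm_perwoman_loglik <- function(th, ss) {
  beta <- th[1:7]
  L <- matrix(c(th[8], th[9], 0, th[10]), 2, 2)
  G <- L %*% t(L)
  s2 <- exp(th[11])
  idx <- split(seq_along(ss$y), ss$id)
  vapply(idx, function(i) {
    Xi <- ss$X[i, , drop = FALSE]
    Zi <- cbind(1, ss$a[i])
    Vi <- Zi %*% G %*% t(Zi) + s2 * diag(length(i))
    ri <- as.numeric(ss$y[i] - Xi %*% beta)
    cf <- chol(Vi)
    u <- backsolve(cf, ri, transpose = TRUE)
    -0.5 * (length(i) * log(2 * pi) + 2 * sum(log(diag(cf))) + sum(u * u))
  }, numeric(1))
}

#' Write / read LMM parameters as JSON
#'
#' The exchange format consumed by the prediction stage:
#' `{"beta": [...7...], "G": [[..],[..]], "sigma2": s, "centering": c}`.
#'
#' @param params an [lmm_params()] object
#' @param path JSON file path
#' @return `write_lmm_params` the path, invisibly; `read_lmm_params` an
#'   [lmm_params()] object.
#' @export
write_lmm_params <- function(params, path) {
  jsonlite::write_json(
    list(beta = params$beta, G = params$G, sigma2 = params$sigma2,
         centering = params$centering),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lmm_params
#' @export
read_lmm_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  G <- j$G
  if (is.list(G)) G <- do.call(rbind, lapply(G, unlist))
  lmm_params(j$beta, matrix(as.numeric(G), 2, 2), j$sigma2, j$centering)
}
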