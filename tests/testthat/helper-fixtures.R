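# Shared fixtures and independent oracles, all built in code.

# two-woman, five-screen toy cohort with complete data
toy_cohort <- function() {
  screens <- data.frame(
    woman_id = c("a", "a", "a", "b", "b"),
    exam_time = c(0, 1.5, 3.2, 0, 2.1),
    age = c(45, 46.5, 48.2, 60, 62.1),
    bmi = c(24, 25, 25.5, 31, 30),
    birads = c(3, 2, 3, 2, 2))
  outcomes <- data.frame(
    woman_id = c("a", "b"),
    exit_time = c(5, 4),
    event = c(1, 0),
    censor_reason = c("none", "admin_end"))
  cohort_table(screens, outcomes)
}

# random small complete cohort (no missingness), n women, 1..max_k screens
random_cohort <- function(n = 10, max_k = 5, seed = 1) {
  set.seed(seed)
  screens <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(max_k, 1)
    gaps <- round(runif(k - 1, 0.8, 2.5), 3)
    times <- cumsum(c(0, gaps))
    age0 <- runif(1, 41, 70)
    data.frame(woman_id = sprintf("w%03d", i), exam_time = times,
               age = age0 + times, bmi = round(runif(k, 18, 34), 1),
               birads = sample(1:4, k, replace = TRUE))
  }))
  last <- tapply(screens$exam_time, screens$woman_id, max)
  outcomes <- data.frame(
    woman_id = names(last),
    exit_time = as.numeric(last) + round(runif(n, 0.6, 4), 3),
    event = rbinom(n, 1, 0.3))
  outcomes$censor_reason <- ifelse(outcomes$event == 1, "none", "admin_end")
  cohort_table(screens, outcomes)
}

test_params <- function() {
  lmm_params(beta = c(3.6, -0.1, -0.01, 0.002, -1e-4, -0.035, 0.002),
             G = matrix(c(0.4, -0.01, -0.01, 0.006), 2, 2),
             sigma2 = 0.18, centering = 10)
}

# dense multivariate-normal log-density oracle: sum over women of
# log N(y_i; X_i beta, Z_i G Z_i' + s2 I), by brute-force dense algebra
dense_loglik_oracle <- function(params, cohort) {
  s <- cohort$screens
  total <- 0
  for (id in unique(s$woman_id)) {
    rows <- s[s$woman_id == id, ]
    d <- build_design(rows$age, rows$bmi, params$centering)
    V <- d$z %*% params$G %*% t(d$z) + params$sigma2 * diag(nrow(rows))
    r <- rows$birads - d$x %*% params$beta
    k <- nrow(rows)
    total <- total - 0.5 * (k * log(2 * pi) + determinant(V)$modulus +
                              t(r) %*% solve(V) %*% r)
  }
  as.numeric(total)
}

# dense BLUP oracle for one woman's history: b = G Z' V^-1 (y - X beta)
dense_blup_oracle <- function(x, z, y, params) {
  x <- matrix(x, ncol = 7); z <- matrix(z, ncol = 2)
  V <- z %*% params$G %*% t(z) + params$sigma2 * diag(length(y))
  r <- y - x %*% params$beta
  b <- params$G %*% t(z) %*% solve(V, r)
  cov <- params$G - params$G %*% t(z) %*% solve(V, z %*% params$G)
  list(b_hat = as.numeric(b), b_cov = cov)
}

# brute-force double-loop windowed concordance, mirroring the definition:
# windows [t, t+w) from 0.5; pairs (event, at-risk subject of a different
# woman without an event at that time); ties weight 1/2
brute_concordance <- function(intervals, lp, window = 1.0) {
  start <- intervals$start; stp <- intervals$stop
  event <- intervals$event; woman <- intervals$woman_id
  if (max(stp) < 0.5) return(NULL)
  t0 <- seq(0.5, max(stp), by = window)
  rows <- list()
  for (tw in t0) {
    num <- 0; den <- 0
    pvals <- c(); ms <- c()
    for (e in which(event == 1)) {
      s <- stp[e]
      if (s < tw || s >= tw + window) next
      conc <- 0; m <- 0
      for (j in seq_along(start)) {
        if (j == e) next
        if (woman[j] == woman[e]) next
        if (!(start[j] < s && s <= stp[j])) next
        if (event[j] == 1 && stp[j] == s) next
        m <- m + 1
        if (lp[e] > lp[j]) conc <- conc + 1
        else if (lp[e] == lp[j]) conc <- conc + 0.5
      }
      if (m > 0) { pvals <- c(pvals, conc / m); ms <- c(ms, m) }
    }
    if (length(ms)) {
      yC <- sum(pvals * ms) / sum(ms)
      se <- sqrt(sum(ms^2 * (pvals - yC)^2)) / sum(ms)
      rows[[length(rows) + 1]] <- data.frame(time = tw, yC = yC, se = se,
                                             n_pairs = sum(ms))
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# simple exponential-time survival data (no time-varying covariates) in
# counting-process form, for Cox oracle checks
sim_simple_survival <- function(n = 30, beta = 0.8, seed = 1,
                                binary = TRUE) {
  set.seed(seed)
  x <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  t_ev <- rexp(n, rate = 0.1 * exp(beta * x))
  cens <- runif(n, 2, 12)
  stp <- pmin(t_ev, cens)
  data.frame(woman_id = sprintf("s%03d", seq_len(n)),
             start = 0, stop = stp, event = as.integer(t_ev <= cens),
             x = x)
}
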