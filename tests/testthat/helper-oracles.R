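# Independent numerical oracles and model generators used across tests.

# random stable VAR(1) population model
rand_var_model <- function(n, sr = 0.7, noise_jitter = 0.3) {
  A <- matrix(rnorm(n * n, 0, 0.3), n, n)
  A <- A * sr / max(Mod(eigen(A, only.values = TRUE)$values))
  d <- exp(rnorm(n, 0, noise_jitter))
  var1_population_model(A, noise = diag(d), tau = 1)
}

# Gauss-Hermite rule for the standard normal weight (Golub-Welsch)
gh_rule <- function(k) {
  J <- matrix(0, k, k)
  for (j in seq_len(k - 1)) J[j, j + 1] <- J[j + 1, j] <- sqrt(j)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2)
}

# Monte-Carlo / quadrature oracle for I~(beta) on a 2-node model with the
# 1|2 bipartition: outer expectation over p(x, y) by sampling, inner
# normaliser E_x'[q(y|x')^beta] by 2-D Gauss-Hermite quadrature.
itilde_mc_2node <- function(model, beta, N = 1e5, k = 40) {
  Sx <- model$cov_past; Sy <- model$cov_present; Sxy <- model$cross_cov
  J <- joint_covariance(model)
  Z <- matrix(rnorm(N * 4), ncol = 4) %*% chol(J)
  Y <- Z[, 3:4]
  X <- Z[, 1:2]
  a1 <- Sxy[1, 1] / Sx[1, 1]; v1 <- Sy[1, 1] - Sxy[1, 1]^2 / Sx[1, 1]
  a2 <- Sxy[2, 2] / Sx[2, 2]; v2 <- Sy[2, 2] - Sxy[2, 2]^2 / Sx[2, 2]
  t1 <- beta * (dnorm(Y[, 1], a1 * X[, 1], sqrt(v1), log = TRUE) +
                  dnorm(Y[, 2], a2 * X[, 2], sqrt(v2), log = TRUE))
  g <- gh_rule(k)
  grid <- as.matrix(expand.grid(g$x, g$x))
  wts <- as.vector(outer(g$w, g$w))
  XP <- grid %*% chol(Sx)  # nodes of x' ~ N(0, Sx)
  t2 <- numeric(N)
  for (s in seq(1, N, by = 10000)) {
    e <- min(N, s + 10000 - 1)
    l1 <- outer(Y[s:e, 1], XP[, 1],
                function(y, x) dnorm(y, a1 * x, sqrt(v1), log = TRUE))
    l2 <- outer(Y[s:e, 2], XP[, 2],
                function(y, x) dnorm(y, a2 * x, sqrt(v2), log = TRUE))
    lq <- beta * (l1 + l2)
    mx <- apply(lq, 1, max)
    t2[s:e] <- mx + log((exp(lq - mx) %*% wts)[, 1])
  }
  vals <- t1 - t2
  list(est = mean(vals), se = sd(vals) / sqrt(N))
}

# Monte-Carlo estimate of the mutual information of a lagged model:
# mean of log p(x, y) - log p(x) - log p(y) over samples of the joint.
mi_mc <- function(model, N = 2e5) {
  J <- joint_covariance(model)
  n <- n_channels(model)
  Z <- matrix(rnorm(N * 2 * n), ncol = 2 * n) %*% chol(J)
  ld_mvn <- function(Z, S) {
    R <- chol(S)
    q <- rowSums((Z %*% solve(R))^2)
    -0.5 * q - sum(log(diag(R))) - 0.5 * ncol(Z) * log(2 * pi)
  }
  vals <- ld_mvn(Z, J) - ld_mvn(Z[, 1:n, drop = FALSE], model$cov_past) -
    ld_mvn(Z[, (n + 1):(2 * n), drop = FALSE], model$cov_present)
  list(est = mean(vals), se = sd(vals) / sqrt(N))
}

# fabricate a cohort table for the statistics layer (values supplied per
# subject x condition as a function of step)
toy_cohort <- function(subjects, conditions = c("SYNC", "ASYNC"), total = 12,
                       value_fun, cut_fun = NULL) {
  rows <- list()
  for (sj in subjects) for (cond in conditions) {
    steps <- seq_len(total)
    df <- data.frame(subject_id = sj, condition = cond, step = steps,
                     phase = phase_of_step(steps, total),
                     stringsAsFactors = FALSE)
    df$phi_mip <- value_fun(sj, cond, steps)
    df$sum_main_phi <- df$phi_mip
    df$mip_cut <- if (is.null(cut_fun)) "a|b" else cut_fun(sj, cond, steps)
    df$max_main_subset <- df$mip_cut
    rows[[length(rows) + 1]] <- df
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_series", "data.frame")
  out
}
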