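#' Lagged Gaussian model of a multichannel window
#'
#' Second-order statistics of the pair (X(t-tau), X(t)) for a set of
#' channels: the covariance of the past state, the covariance of the
#' present state, and their cross-covariance.  This object is the sole
#' input to all integrated-information computations.
#'
#' @param cov_past,cov_present n x n covariance matrices of X(t-tau) and
#'   X(t).
#' @param cross_cov n x n matrix with entry (i, j) = Cov(X_i(t-tau),
#'   X_j(t)).
#' @param labels character vector of channel names (length n).
#' @param tau lag in frames (non-negative integer).
#' @param n_samples number of frame pairs the statistics were estimated
#'   from (NA for population models).
#' @param ridge regularisation already added to the diagonals of the two
#'   marginal blocks.
#'
#' @return An object of class `lagged_model`.
#' @export
lagged_model <- function(cov_past, cov_present, cross_cov, labels = NULL,
                         tau = 1L, n_samples = NA_integer_, ridge = 0) {
  cov_past <- as.matrix(cov_past)
  cov_present <- as.matrix(cov_present)
  cross_cov <- as.matrix(cross_cov)
  n <- nrow(cov_past)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  stopifnot(
    ncol(cov_past) == n,
    all(dim(cov_present) == c(n, n)),
    all(dim(cross_cov) == c(n, n)),
    length(labels) == n,
    tau >= 0, ridge >= 0
  )
  if (max(abs(cov_past - t(cov_past))) > 1e-8 * (1 + max(abs(cov_past))) ||
      max(abs(cov_present - t(cov_present))) > 1e-8 * (1 + max(abs(cov_present))))
    stop("cov_past and cov_present must be symmetric")
  structure(
    list(
      labels = as.character(labels), tau = as.integer(tau),
      cov_past = (cov_past + t(cov_past)) / 2,
      cov_present = (cov_present + t(cov_present)) / 2,
      cross_cov = cross_cov,
      n_samples = n_samples, ridge = ridge
    ),
    class = "lagged_model"
  )
}

#' @export
print.lagged_model <- function(x, ...) {
  cat(sprintf(
    "<lagged_model> %d channels (%s), tau = %d, n_samples = %s, ridge = %g\n",
    length(x$labels), paste(x$labels, collapse = ", "), x$tau,
    ifelse(is.na(x$n_samples), "NA", format(x$n_samples)), x$ridge
  ))
  invisible(x)
}

#' Number of channels of a lagged model
#' @param model a [lagged_model()].
#' @export
n_channels <- function(model) length(model$labels)

#' Estimate a lagged Gaussian model from a window of data
#'
#' Forms the paired samples (x(t - tau), x(t)) for t = tau + 1, ..., T,
#' subtracts the mean of each channel in each member of the pair, and
#' computes maximum-likelihood covariances (divide by the number of pairs).
#' A ridge is added to the diagonals of the two marginal covariance blocks
#' to keep near-degenerate windows invertible.
#'
#' @param window numeric matrix, frames x channels.
#' @param tau lag in frames; the window must have at least `tau + 2` rows.
#' @param ridge non-negative scalar added to the marginal diagonals;
#'   `NULL` (default) uses `1e-8 * mean(diag(cov))`.
#' @param labels channel names; defaults to `colnames(window)`.
#'
#' @return A [lagged_model()].
#' @examples
#' w <- matrix(rnorm(600), ncol = 3)
#' estimate_lagged_model(w, tau = 1)
#' @export
estimate_lagged_model <- function(window, tau = 50L, ridge = NULL,
                                  labels = colnames(window)) {
  window <- as.matrix(window)
  T_len <- nrow(window)
  n <- ncol(window)
  if (n < 2) stop("need at least 2 channels")
  tau <- as.integer(tau)
  if (tau < 0) stop("tau must be non-negative")
  if (T_len < tau + 2)
    stop(sprintf("window too short: %d frames for tau = %d (need >= %d)",
                 T_len, tau, tau + 2))
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))

  sds <- apply(window, 2, sd)
  if (any(sds == 0)) {
    bad <- labels[sds == 0]
    stop(sprintf("constant (zero-variance) channel(s): %s",
                 paste(bad, collapse = ", ")))
  }

  m <- T_len - tau
  xp <- window[seq_len(m), , drop = FALSE]
  xc <- window[(tau + 1):T_len, , drop = FALSE]
  xp <- sweep(xp, 2, colMeans(xp))
  xc <- sweep(xc, 2, colMeans(xc))
  cov_past <- crossprod(xp) / m
  cov_present <- crossprod(xc) / m
  cross_cov <- crossprod(xp, xc) / m

  if (is.null(ridge)) ridge <- 1e-8 * mean(c(diag(cov_past), diag(cov_present)))
  diag(cov_past) <- diag(cov_past) + ridge
  diag(cov_present) <- diag(cov_present) + ridge

  model <- lagged_model(cov_past, cov_present, cross_cov, labels = labels,
                        tau = tau, n_samples = m, ridge = ridge)
  ev <- eigen(joint_covariance(model), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    warning("joint covariance is near-singular (almost perfectly correlated channels); consider a larger ridge")
  model
}

#' Joint 2n x 2n covariance of (X(t-tau), X(t))
#' @param model a [lagged_model()].
#' @return symmetric 2n x 2n matrix.
#' @export
joint_covariance <- function(model) {
  rbind(
    cbind(model$cov_past, model$cross_cov),
    cbind(t(model$cross_cov), model$cov_present)
  )
}

#' Restrict a lagged model to a subset of channels
#'
#' @param model a [lagged_model()].
#' @param subset integer indices (or labels) of the retained channels.
#' @return A [lagged_model()] over the sub-blocks of the covariances.
#' @export
restrict_model <- function(model, subset) {
  if (is.character(subset)) subset <- match(subset, model$labels)
  subset <- as.integer(subset)
  if (anyNA(subset) || any(subset < 1) || any(subset > n_channels(model)))
    stop("invalid channel subset")
  lagged_model(
    model$cov_past[subset, subset, drop = FALSE],
    model$cov_present[subset, subset, drop = FALSE],
    model$cross_cov[subset, subset, drop = FALSE],
    labels = model$labels[subset], tau = model$tau,
    n_samples = model$n_samples, ridge = model$ridge
  )
}

#' Population lagged model of a stationary VAR(1) process
#'
#' For x(t) = A x(t-1) + eps, eps ~ N(0, Sigma), the stationary covariance
#' solves the discrete Lyapunov equation S = A S A' + Sigma, and the
#' cross-covariance at lag tau is Cov(x(t-tau), x(t)) = S (A^tau)'.
#' Useful for exact (noise-free) test models.
#'
#' @param A stable n x n coupling matrix (spectral radius < 1).
#' @param noise innovation covariance (default identity).
#' @param tau lag in frames.
#' @param labels channel names.
#' @return A [lagged_model()] with population covariances.
#' @export
var1_population_model <- function(A, noise = diag(nrow(A)), tau = 1L,
                                  labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
    stop("A is not stable (spectral radius >= 1)")
  S <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(noise)), n, n)
  S <- (S + t(S)) / 2
  Ak <- diag(n)
  for (i in seq_len(tau)) Ak <- A %*% Ak
  lagged_model(S, S, S %*% t(Ak), labels = labels, tau = tau)
}
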