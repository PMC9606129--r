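#' Mutual information between past and present states
#'
#' For a Gaussian model, I(X(t-tau); X(t)) = 1/2 log( |Sx| |Sy| / |J| )
#' where J is the joint 2n x 2n covariance.  Returned in nats;
#' non-negative up to numerical tolerance.
#'
#' @param model a [lagged_model()].
#' @return Mutual information in nats.
#' @export
mutual_information <- function(model) {
  stopifnot(inherits(model, "lagged_model"))
  ld <- function(M, what) {
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0 || !is.finite(d$modulus))
      stop(sprintf("non-positive-definite %s; increase the ridge", what))
    as.numeric(d$modulus)
  }
  0.5 * (ld(model$cov_past, "past covariance") +
           ld(model$cov_present, "present covariance") -
           ld(joint_covariance(model), "joint covariance"))
}

#' Mismatched-decoding information I~(beta)
#'
#' The information transmissible about the present state when decoding the
#' past with the partition-factorised model q(x(t) | x(t - tau)) =
#' prod_k p(x_k(t) | x_k(t - tau)), where k runs over the blocks of the
#' partition:
#'
#'   I~(beta) = E_p\[ log( q(y|x)^beta / E_p(x')\[ q(y|x')^beta \] ) \]
#'
#' All expectations are Gaussian integrals and are evaluated in closed
#' form.  `I~(beta) <= I(X(t-tau); X(t))` for all `beta`, and
#' `I~(beta) -> 0` as `beta -> 0`.
#'
#' @param model a [lagged_model()].
#' @param partition a [bipartition()] of the model's channels (or a plain
#'   list of index blocks forming a partition).
#' @param beta positive scalar decoding exponent.
#' @return I~(beta) in nats.
#' @export
mismatched_information <- function(model, partition, beta) {
  stopifnot(inherits(model, "lagged_model"), beta > 0)
  blocks <- partition_blocks(partition, n_channels(model))
  Sx <- model$cov_past
  Sy <- model$cov_present
  Sxy <- model$cross_cov
  Syx <- t(Sxy)
  n <- nrow(Sx)

  H <- matrix(0, n, n)
  Q <- matrix(0, n, n)
  for (b in blocks) {
    Sxb <- Sx[b, b, drop = FALSE]
    ok <- tryCatch(solve(Sxb), error = function(e) NULL)
    if (is.null(ok)) stop("singular past block covariance; increase the ridge")
    Hb <- Syx[b, b, drop = FALSE] %*% ok
    H[b, b] <- Hb
    Db <- Sy[b, b, drop = FALSE] - Hb %*% Sxy[b, b, drop = FALSE]
    Qb <- tryCatch(solve(Db), error = function(e) NULL)
    if (is.null(Qb)) stop("singular conditional block covariance; increase the ridge")
    Q[b, b] <- Qb
  }
  R <- Sy - H %*% Sxy - Syx %*% t(H) + H %*% Sx %*% t(H)
  K <- t(H) %*% Q %*% H
  W <- t(H) %*% Q %*% Sy %*% Q %*% H
  M <- solve(Sx) + beta * K
  ldet <- determinant(diag(n) + beta * Sx %*% K, logarithm = TRUE)
  if (ldet$sign <= 0) stop("non-positive-definite decoder term; increase the ridge")
  -0.5 * beta * sum(diag(Q %*% R)) +
    0.5 * beta * sum(diag(Q %*% Sy)) +
    0.5 * as.numeric(ldet$modulus) -
    0.5 * beta^2 * sum(diag(solve(M, W)))
}

# normalise a partition argument to a list of integer blocks covering 1..n
partition_blocks <- function(partition, n) {
  if (inherits(partition, "bipartition")) {
    if (partition$n != n) stop("partition is over a different number of nodes")
    return(list(partition$block_a, partition$block_b))
  }
  blocks <- lapply(partition, function(b) sort(as.integer(b)))
  if (!identical(sort(unlist(blocks)), seq_len(n)))
    stop("blocks must partition 1..n")
  blocks
}

#' Integrated information Phi* across one partition
#'
#' Phi*(pi) = I(X(t-tau); X(t)) - max_beta I~(beta), with the scalar beta
#' maximised over `(0, beta_max]` by golden-section search.  Phi* is
#' non-negative (up to numerical tolerance) and never exceeds the mutual
#' information.
#'
#' @param model a [lagged_model()].
#' @param partition a [bipartition()].
#' @param beta_max upper bracket of the beta search (default 32).
#' @param tol absolute tolerance of the beta search (default 1e-8).
#' @return List with elements `phi`, `beta_opt`, `itilde` and
#'   `mutual_info` (all information in nats).
#' @export
phi_star <- function(model, partition, beta_max = 32, tol = 1e-8) {
  stopifnot(inherits(model, "lagged_model"))
  blocks <- partition_blocks(partition, n_channels(model))
  v <- cpp_phi_partition(model$cov_past, model$cov_present, model$cross_cov,
                         blocks, beta_max, tol)
  as.list(v)
}

#' Exhaustive minimum information partition search
#'
#' Enumerates all `2^(n-1) - 1` unordered bipartitions of the model's
#' channels, computes Phi* across each, and returns the minimiser (the
#' MIP, the system's weakest link).  Ties are broken towards the earliest
#' partition in the order of [enumerate_bipartitions()].
#'
#' @param model a [lagged_model()] with at least 2 channels.
#' @param beta_max,tol passed to the beta search (see [phi_star()]).
#' @param per_partition keep the full per-partition table (default TRUE).
#' @return An object of class `phi_result`: a list with `phi_mip`, `mip`
#'   (a [bipartition()]), `mip_cut` (its label), `mutual_info`, `beta_opt`
#'   and, optionally, `per_partition` (data frame with one row per
#'   bipartition).
#' @examples
#' m <- var1_population_model(matrix(c(0.5, 0.3, 0.3, 0.5), 2), tau = 1)
#' mip_search(m)
#' @export
mip_search <- function(model, beta_max = 32, tol = 1e-8, per_partition = TRUE) {
  stopifnot(inherits(model, "lagged_model"))
  n <- n_channels(model)
  if (n < 2) stop("need at least 2 channels")
  tab <- cpp_mip_all(model$cov_past, model$cov_present, model$cross_cov,
                     beta_max, tol)
  mi <- cpp_mutual_information(model$cov_past, model$cov_present,
                               model$cross_cov)
  best <- which.min(tab[, 1])
  mip <- bipartition_from_mask(best, n)
  res <- list(
    phi_mip = tab[best, 1],
    mip = mip,
    mip_cut = format_bipartition(mip, model$labels),
    mutual_info = mi,
    beta_opt = tab[best, 2]
  )
  if (per_partition) {
    parts <- enumerate_bipartitions(n)
    res$per_partition <- data.frame(
      partition = vapply(parts, format_bipartition, "", labels = model$labels),
      phi = tab[, 1],
      beta_opt = tab[, 2],
      stringsAsFactors = FALSE
    )
  }
  structure(res, class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("<phi_result> Phi_MIP = %.6g nats at cut %s (I = %.6g, beta* = %.3g)\n",
              x$phi_mip, x$mip_cut, x$mutual_info, x$beta_opt))
  invisible(x)
}
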