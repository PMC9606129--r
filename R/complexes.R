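#' Phi_MIP for every subsystem
#'
#' Runs the exhaustive MIP search on the restricted model of every channel
#' subset of size >= 2 (`2^n - n - 1` subsets; 120 for the seven-channel
#' system).  Exhaustive enumeration is intended for n <= 12.
#'
#' @param model a [lagged_model()].
#' @param beta_max,tol beta-search controls, see [phi_star()].
#' @return Data frame with one row per subset: `key` (comma-separated
#'   indices), `label`, `mask` (bitmask over channels), `size`, `phi_mip`,
#'   `mip_cut`, `beta_opt`, `mutual_info`, and a list column `nodes`.
#' @export
subset_phi_all <- function(model, beta_max = 32, tol = 1e-8) {
  stopifnot(inherits(model, "lagged_model"))
  n <- n_channels(model)
  if (n > 12) stop("exhaustive subset enumeration is limited to n <= 12")
  subsets <- enumerate_subsets(n)
  tab <- cpp_subset_report(model$cov_past, model$cov_present, model$cross_cov,
                           subsets, beta_max, tol)
  mip_cut <- character(length(subsets))
  for (i in seq_along(subsets)) {
    nodes <- subsets[[i]]
    local_bp <- bipartition_from_mask(tab[i, 2], length(nodes))
    global_bp <- bipartition_raw(nodes[local_bp$block_a], nodes[local_bp$block_b])
    mip_cut[i] <- format_bipartition(global_bp, model$labels)
  }
  out <- data.frame(
    key = vapply(subsets, paste, "", collapse = ","),
    label = vapply(subsets, function(s) paste(model$labels[s], collapse = ","), ""),
    mask = vapply(subsets, function(s) sum(2^(s - 1)), 0),
    size = lengths(subsets),
    phi_mip = tab[, 1],
    mip_cut = mip_cut,
    beta_opt = tab[, 3],
    mutual_info = tab[, 4],
    stringsAsFactors = FALSE
  )
  out$nodes <- subsets
  attr(out, "n") <- n
  attr(out, "labels") <- model$labels
  out
}

# all subsets of 1..n with >= 2 elements, ascending bitmask order
enumerate_subsets <- function(n) {
  masks <- seq_len(2^n - 1)
  subsets <- lapply(masks, function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  subsets[lengths(subsets) >= 2]
}

# bipartition over arbitrary (global) index sets; no 1..n completeness check
bipartition_raw <- function(a, b) {
  a <- sort(as.integer(a)); b <- sort(as.integer(b))
  if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
  structure(list(block_a = a, block_b = b, n = length(a) + length(b)),
            class = "bipartition")
}

#' Find the complexes of a system
#'
#' A complex is a subsystem T with Phi_MIP(T) > 0 that is more integrated
#' than every strict superset: Phi_MIP(T) > Phi_MIP(R) for all R with
#' T proper-subset R (|R| >= 2).  The whole system qualifies whenever its
#' Phi_MIP is positive, the superset condition being vacuous.
#'
#' @param subset_phis complete subset table from [subset_phi_all()].
#' @param eps_pos positivity threshold for "Phi_MIP > 0" (default 1e-10);
#'   strict positivity is numerically meaningless.
#' @return The rows of `subset_phis` that are complexes.
#' @export
find_complexes <- function(subset_phis, eps_pos = 1e-10) {
  n <- attr(subset_phis, "n")
  if (is.null(n)) n <- max(unlist(subset_phis$nodes))
  if (nrow(subset_phis) != 2^n - n - 1)
    stop("incomplete subset table: expected one row per subset of size >= 2")
  masks <- subset_phis$mask
  phi <- subset_phis$phi_mip
  is_complex <- logical(length(masks))
  for (i in seq_along(masks)) {
    if (phi[i] <= eps_pos) next
    sup <- which(bitwAnd(masks, masks[i]) == masks[i] & masks != masks[i])
    is_complex[i] <- all(phi[i] > phi[sup])
  }
  out <- subset_phis[is_complex, , drop = FALSE]
  attr(out, "n") <- n
  attr(out, "labels") <- attr(subset_phis, "labels")
  out
}

#' Find the main complexes among the complexes
#'
#' A main complex is a complex that is more integrated than every one of
#' its subsystems.  Among complexes this is equivalent to containing no
#' other complex as a strict subset, which is the criterion implemented;
#' the direct definition (compare against all subsets of size >= 2) is
#' available via `method = "direct"` for verification.
#'
#' @param complexes output of [find_complexes()].
#' @param subset_phis the full table from [subset_phi_all()] (required for
#'   `method = "direct"`).
#' @param method `"shortcut"` (default) or `"direct"`.
#' @return The rows of `complexes` that are main complexes.  Main
#'   complexes are pairwise disjoint.
#' @export
find_main_complexes <- function(complexes, subset_phis = NULL,
                                method = c("shortcut", "direct")) {
  method <- match.arg(method)
  masks <- complexes$mask
  if (method == "shortcut") {
    keep <- vapply(seq_along(masks), function(i) {
      inside <- bitwAnd(masks, masks[i]) == masks & masks != masks[i]
      !any(inside)
    }, TRUE)
  } else {
    if (is.null(subset_phis)) stop("method = 'direct' needs the full subset table")
    keep <- vapply(seq_along(masks), function(i) {
      sub <- which(bitwAnd(subset_phis$mask, masks[i]) == subset_phis$mask &
                     subset_phis$mask != masks[i])
      all(complexes$phi_mip[i] > subset_phis$phi_mip[sub])
    }, TRUE)
  }
  out <- complexes[keep, , drop = FALSE]
  attr(out, "n") <- attr(complexes, "n")
  attr(out, "labels") <- attr(complexes, "labels")
  out
}

#' Full complex analysis of one window
#'
#' Computes Phi_MIP for every subsystem, extracts the complexes and main
#' complexes, and summarises the sum of Phi_MIP over main complexes (the
#' subsystem-integrity measure) and the strongest main complex.
#'
#' @param model a [lagged_model()].
#' @param beta_max,tol,eps_pos see [subset_phi_all()] and
#'   [find_complexes()].
#' @return An object of class `complex_report`: list with `subset_phis`,
#'   `complexes`, `main_complexes`, `sum_main_phi`, `n_complexes`,
#'   `n_main_complexes` and `max_main` (list with `label`, `nodes`,
#'   `phi_mip`; `NULL` when there is no main complex).
#' @export
summarize_complexes <- function(model, beta_max = 32, tol = 1e-8,
                                eps_pos = 1e-10) {
  sp <- subset_phi_all(model, beta_max = beta_max, tol = tol)
  cx <- find_complexes(sp, eps_pos = eps_pos)
  mc <- find_main_complexes(cx)
  max_main <- NULL
  if (nrow(mc) > 0) {
    i <- which.max(mc$phi_mip)
    max_main <- list(label = mc$label[i], nodes = mc$nodes[[i]],
                     phi_mip = mc$phi_mip[i])
  }
  structure(
    list(
      subset_phis = sp, complexes = cx, main_complexes = mc,
      sum_main_phi = sum(mc$phi_mip),
      n_complexes = nrow(cx), n_main_complexes = nrow(mc),
      max_main = max_main
    ),
    class = "complex_report"
  )
}

#' @export
print.complex_report <- function(x, ...) {
  cat(sprintf("<complex_report> %d complexes, %d main complexes, sum Phi = %.6g\n",
              x$n_complexes, x$n_main_complexes, x$sum_main_phi))
  if (!is.null(x$max_main))
    cat(sprintf("  strongest main complex: {%s} with Phi_MIP = %.6g\n",
                x$max_main$label, x$max_main$phi_mip))
  invisible(x)
}
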