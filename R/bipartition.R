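#' Bipartition of a node set
#'
#' An unordered two-block split of the nodes `1..n`.  The canonical form
#' stores the block containing the smallest index as `block_a`, both blocks
#' sorted.
#'
#' @param block_a,block_b disjoint non-empty integer index sets whose union
#'   is `1..n`.
#' @return An object of class `bipartition` with elements `block_a`,
#'   `block_b` and `n`.
#' @examples
#' bipartition(c(2, 1), c(3, 4))
#' @export
bipartition <- function(block_a, block_b) {
  a <- sort(unique(as.integer(block_a)))
  b <- sort(unique(as.integer(block_b)))
  if (length(a) == 0 || length(b) == 0) stop("both blocks must be non-empty")
  if (length(intersect(a, b)) > 0) stop("blocks must be disjoint")
  full <- sort(c(a, b))
  n <- length(full)
  if (!identical(full, seq_len(n)))
    stop("blocks must partition 1..n")
  if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
  structure(list(block_a = a, block_b = b, n = n), class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf("<bipartition> {%s} | {%s}\n",
              paste(x$block_a, collapse = ","),
              paste(x$block_b, collapse = ",")))
  invisible(x)
}

#' Enumerate all unordered bipartitions of n nodes
#'
#' There are `2^(n-1) - 1` of them.  Node 1 is always placed in `block_a`;
#' candidate `block_b` sets run over the non-empty subsets of `2..n` in
#' ascending binary-mask order (bit j-2 of the mask selects node j).  This
#' fixed order is also the tie-breaking order of [mip_search()].
#'
#' @param n number of nodes (>= 2).
#' @return List of [bipartition()] objects.
#' @examples
#' length(enumerate_bipartitions(7)) # 63
#' @export
enumerate_bipartitions <- function(n) {
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 nodes")
  lapply(seq_len(2^(n - 1) - 1), function(m) bipartition_from_mask(m, n))
}

# mask m in 1..2^(n-1)-1: bit j-2 set => node j in block_b (node 1 in block_a)
bipartition_from_mask <- function(m, n) {
  bits <- bitwAnd(m, 2^(0:(n - 2))) > 0
  b <- which(bits) + 1L
  bipartition(setdiff(seq_len(n), b), b)
}

# inverse of bipartition_from_mask
bipartition_mask <- function(bp) {
  sum(2^(bp$block_b - 2L))
}

#' Format a bipartition as a cut label
#'
#' @param bp a [bipartition()].
#' @param labels channel names to substitute for indices.
#' @return A string of the form `"A,B,C|D"`.
#' @export
format_bipartition <- function(bp, labels = NULL) {
  fmt <- function(idx) {
    if (is.null(labels)) paste(idx, collapse = ",")
    else paste(labels[idx], collapse = ",")
  }
  paste0(fmt(bp$block_a), "|", fmt(bp$block_b))
}
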