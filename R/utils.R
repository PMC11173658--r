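#' @keywords internal
"_PACKAGE"

# Round half away from zero. base::round() rounds half to even, which would
# make mask counts like round(0.5 * 10) depend on parity; augmentation and
# top-K contracts require the arithmetic convention.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a reproducible 32-bit sub-seed from a base seed and stream indices.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 48271 + (as.numeric(k) %% 2147483647) + 11) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

vlog <- function(...) {
  if (isTRUE(getOption("mphgcl.verbose", FALSE))) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-triangle edge list of a symmetric binary adjacency.
adj_to_edges <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

edges_to_adj <- function(edges, n) {
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[edges] <- 1
    A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}
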