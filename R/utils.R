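# Internal helpers shared across modules.

# Wrap angles (degrees) into (-180, 180].
wrap_deg <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  # %% can yield exactly -180 via floating point; map to +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# Derive a child RNG seed from a master seed and a stream index.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) * 48271 + as.double(index) * 104729) %% 2147483629
  as.integer(s) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Dense numeric matrix from a possibly sparse Matrix object.
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

is_square <- function(m) length(dim(m)) == 2 && nrow(m) == ncol(m)

# Triplet (i, j, x) representation of the nonzero entries of any matrix.
# Coerces through generalMatrix first: symmetric/triangular storage classes
# would otherwise drop half the entries from summary().
as_triplets <- function(M) {
  S <- Matrix::summary(methods::as(methods::as(
    Matrix::Matrix(M, sparse = TRUE), "generalMatrix"), "TsparseMatrix"))
  S[S$x != 0, , drop = FALSE]
}

check_row_stochastic <- function(T, tol = 1e-8) {
  rs <- Matrix::rowSums(T)
  if (any(abs(rs - 1) > tol))
    stopf("matrix is not row-stochastic: row %d sums to %.12g",
          which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  invisible(TRUE)
}
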