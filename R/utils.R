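# Internal helpers.

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so that no function disturbs global reproducibility.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Symmetrize, eigendecompose, sort descending, and fix signs so the
# largest-magnitude entry of each eigenvector is positive (deterministic
# tie-break).
symEigen <- function(R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  for (j in seq_len(ncol(e$vectors))) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) e$vectors[, j] <- -v
  }
  e
}

# Symmetric orthonormalization W (W^T W)^{-1/2} via SVD.
orthonormalize <- function(W) {
  sv <- svd(W)
  sv$u %*% t(sv$v)
}

defaultChannelLabels <- function(m) {
  std <- c("Fz", "Cz", "Pz", "Oz", "P7", "P3", "P4", "P8")
  if (m == length(std)) std else sprintf("ch%d", seq_len(m))
}

stopDim <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
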