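# Shared numerical helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code never
# perturbs user-level reproducibility.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Separable 3-D Gaussian blur with zero padding; `sigma` in voxels (scalar
# or per-axis).  Implemented as one banded kernel-matrix product per axis.
gaussian_blur3d <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- d[ax]
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    km <- matrix(0, n, n)
    for (off in seq(-half, half)) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1L & j <= n
      km[cbind(idx[ok], j[ok])] <- km[cbind(idx[ok], j[ok])] + k[off + half + 1L]
    }
    arr <- apply_along_axis(arr, ax, function(m) km %*% m)
  }
  arr
}

# Apply `f` to a (n_ax x rest) matrix view of `arr` along axis `ax`.
apply_along_axis <- function(arr, ax, f) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = d[ax])
  m <- f(m)
  arr2 <- array(m, d[perm])
  aperm(arr2, order(perm))
}

# Integer-voxel translation with zero fill: out[i] = arr[i - offset].
shift_array <- function(arr, offset, fill = 0) {
  d <- dim(arr)
  offset <- as.integer(round(offset))
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    dst[[ax]] <- max(1L, 1L + offset[ax]):min(d[ax], d[ax] + offset[ax])
    if (length(dst[[ax]]) < 1L || dst[[ax]][1L] > d[ax]) return(out)
    src[[ax]] <- dst[[ax]] - offset[ax]
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- arr[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Row-wise log-sum-exp of a matrix, guarding all -Inf rows.
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(-Inf)))
  mx_safe <- ifelse(is.finite(mx), mx, 0)
  lse <- mx_safe + log(rowSums(exp(m - mx_safe)))
  ifelse(is.finite(mx), lse, -Inf)
}

# Voxel-center coordinate arrays scaled to [0, 1] per axis.
unit_coords <- function(d) {
  u <- function(n) if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  list(x = array(rep(u(d[1L]), times = d[2L] * d[3L]), d),
       y = array(rep(rep(u(d[2L]), each = d[1L]), times = d[3L]), d),
       z = array(rep(u(d[3L]), each = d[1L] * d[2L]), d))
}
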