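# Shared fixtures and independent (naive, per-voxel) oracle
# implementations used by the unit and acceptance tests.  The oracles
# deliberately use explicit loops and base formulas so they share no code
# path with the package internals they check.

smooth_random_volume <- function(seed, n = 32, sigma = 2.5) {
  set.seed(seed)
  arr <- array(stats::rnorm(n^3), rep(n, 3L))
  mri_volume(emtseg:::gaussian_blur3d(arr, sigma) * 100 + 100)
}

# registration fixture: fixed is a centre crop of a larger smooth parent
# volume and moving is sampled from the parent through `tft`, so moving has
# valid data everywhere (resampling fixed itself would inject zero-filled
# bands that bias any similarity metric toward shrinking transforms)
reg_pair <- function(seed, tft, n = 32, pad = 6) {
  set.seed(seed)
  big <- emtseg:::gaussian_blur3d(array(stats::rnorm((n + 2 * pad)^3),
                                        rep(n + 2 * pad, 3L)), 2.5) * 100 + 100
  parent <- mri_volume(big)
  idx <- (pad + 1):(pad + n)
  fixed <- mri_volume(big[idx, idx, idx], origin = rep(pad, 3L))
  moving <- resample(parent, tft, fixed)
  list(fixed = fixed, moving = moving,
       center = fixed$origin + (rep(n, 3L) - 1) / 2)
}

small_phantom <- function(n = 32, pn = 3, rf = 20, blur = 1.5,
                          offset = c(0, 0, 0), seed = 1, repeats = 1) {
  generate_phantom_session(phantom_spec(n = n, pn = pn, rf = rf,
                                        prior_blur = blur,
                                        prior_offset = offset,
                                        repeats = repeats, seed = seed))
}

random_stack <- function(seed, n_vox, K, dim3) {
  set.seed(seed)
  p <- matrix(stats::runif(n_vox * K), n_vox, K)
  p <- p / rowSums(p)
  prob_stack(p, paste0("c", seq_len(K)), dim3)
}

# --- naive per-voxel oracles -------------------------------------------

naive_mvn_density <- function(y, mu, sigma) {
  M <- length(y)
  d <- y - mu
  exp(-0.5 * as.numeric(t(d) %*% solve(sigma) %*% d)) /
    sqrt((2 * pi)^M * det(sigma))
}

naive_e_step <- function(Y, mu, sigma, prior) {
  N <- nrow(Y); K <- nrow(mu)
  post <- matrix(0, N, K)
  ll <- 0
  for (i in seq_len(N)) {
    num <- numeric(K)
    for (l in seq_len(K)) {
      if (prior[i, l] > 0)
        num[l] <- naive_mvn_density(Y[i, ], mu[l, ], sigma[[l]]) * prior[i, l]
    }
    s <- sum(num)
    post[i, ] <- if (s > 0) num / s else prior[i, ]
    if (s > 0) ll <- ll + log(s)
  }
  list(post = post, loglik = ll)
}

naive_m_step <- function(Y, P, reg = 1e-6) {
  K <- ncol(P); M <- ncol(Y)
  delta <- reg * mean(apply(Y, 2, stats::var))
  mu <- matrix(0, K, M)
  sigma <- vector("list", K)
  for (l in seq_len(K)) {
    mass <- sum(P[, l])
    for (m in seq_len(M)) mu[l, m] <- sum(P[, l] * Y[, m]) / mass
    S <- matrix(0, M, M)
    for (i in seq_len(nrow(Y))) {
      d <- Y[i, ] - mu[l, ]
      S <- S + P[i, l] * (d %*% t(d))
    }
    sigma[[l]] <- S / mass + delta * diag(M)
  }
  list(mu = mu, sigma = sigma)
}

naive_constrain <- function(prior, ind) {
  out <- prior
  for (i in seq_len(nrow(prior))) {
    v <- prior[i, ] * ind[i, ]
    out[i, ] <- if (sum(v) > 0) v / sum(v) else prior[i, ]
  }
  out
}

naive_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
}

# brute-force modified Hausdorff on boundary sets (mm)
naive_mhd <- function(a, b, spacing) {
  bnd <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!m[i, j, k]) next
      edge <- i == 1 || j == 1 || k == 1 || i == d[1] || j == d[2] || k == d[3]
      if (!edge) {
        edge <- !(m[i - 1, j, k] && m[i + 1, j, k] && m[i, j - 1, k] &&
                  m[i, j + 1, k] && m[i, j, k - 1] && m[i, j, k + 1])
      }
      if (edge) out <- rbind(out, c(i, j, k))
    }
    out
  }
  pa <- sweep(bnd(a) - 1, 2, spacing, "*")
  pb <- sweep(bnd(b) - 1, 2, spacing, "*")
  dmean <- function(x, y) {
    tot <- 0
    for (i in seq_len(nrow(x)))
      tot <- tot + sqrt(min(colSums((t(y) - x[i, ])^2)))
    tot / nrow(x)
  }
  max(dmean(pa, pb), dmean(pb, pa))
}
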