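session_from_arrays <- function(...) {
  arrs <- list(...)
  image_session(lapply(arrs, mri_volume))
}

test_that("quantile_threshold matches the sort-and-interpolate oracle", {
  v <- mri_volume(array(c(1, 2, 3, 4, 5, 9, 9, 9), c(2, 2, 2)))
  mask <- array(c(rep(TRUE, 5), rep(FALSE, 3)), c(2, 2, 2))
  expect_equal(quantile_threshold(v, mask, 0.5), 3)
  expect_equal(quantile_threshold(v, mask, 0), 1)
  expect_equal(quantile_threshold(v, mask, 1), 5)
  expect_equal(quantile_threshold(v, mask, 0.25), naive_quantile(1:5, 0.25))
  set.seed(7)
  x <- rnorm(101)
  vv <- mri_volume(array(c(x, rep(0, 24)), c(5, 5, 5)))
  mk <- array(c(rep(TRUE, 101), rep(FALSE, 24)), c(5, 5, 5))
  for (q in c(0.1, 0.37, 0.5, 0.9))
    expect_equal(quantile_threshold(vv, mk, q), naive_quantile(x, q),
                 tolerance = 1e-12)
  expect_error(quantile_threshold(v, array(FALSE, c(2, 2, 2)), 0.5),
               "empty")
})

test_that("compute_bounds maps configured quantile fractions to intensities", {
  ph <- small_phantom(n = 16, pn = 0, rf = 0, blur = 0)
  mask <- ph$labels$data > 0
  sess <- ph$session
  bounds <- compute_bounds(sess, ph$config, mask)
  t1 <- session_fused(sess)$T1$data[mask]
  # Wm row: (0.5, 1) -> masked median; fraction 1 is the unbounded sentinel
  expect_equal(bounds$lower["Wm", "T1"], unname(quantile(t1, 0.5, type = 7)))
  expect_identical(bounds$upper["Wm", "T1"], Inf)
  # Air row: (0, 0.1) -> no lower constraint, upper at the 0.1 quantile
  expect_identical(bounds$lower["Air", "T1"], -Inf)
  expect_equal(bounds$upper["Air", "T1"],
               unname(quantile(t1, 0.1, type = 7)))
  # interior fractions still map through the masked histogram
  expect_equal(bounds$upper["Csf", "T1"],
               unname(quantile(t1, 0.6, type = 7)))
})

test_that("indicator is a strict conjunction across modalities", {
  # 4 voxels, 2 modalities; bounds for tissue A: T1 in (2, 8), T2 in (10, 40)
  t1 <- array(c(5, 1, 5, 9), c(4, 1, 1))
  t2 <- array(c(20, 20, 50, 20), c(4, 1, 1))
  sess <- session_from_arrays(T1 = t1, T2 = t2)
  bounds <- structure(list(
    lower = matrix(c(2, 10), 1, 2, dimnames = list("A", c("T1", "T2"))),
    upper = matrix(c(8, 40), 1, 2, dimnames = list("A", c("T1", "T2"))),
    modalities = c("T1", "T2")), class = "context_bounds")
  ind <- indicator(sess, bounds, "A")
  # only voxel 1 passes both; failing one modality fails the conjunction
  expect_equal(as.numeric(ind$data), c(1, 0, 0, 0))
  # boundary values are excluded (strict inequalities)
  t1b <- array(c(2, 8, 3, 3), c(4, 1, 1))
  t2b <- array(c(20, 20, 10, 40), c(4, 1, 1))
  indb <- indicator(session_from_arrays(T1 = t1b, T2 = t2b), bounds, "A")
  expect_equal(as.numeric(indb$data), c(0, 0, 0, 0))
})

test_that("constrain_priors matches the naive per-voxel evaluation", {
  set.seed(5)
  n <- 8^3
  st <- random_stack(5, n, 4, c(8, 8, 8))
  ind <- matrix(rbinom(n * 4, 1, 0.6), n, 4)
  got <- constrain_priors(st, ind)
  want <- naive_constrain(st$p, ind)
  expect_lt(max(abs(got$p - want)), 1e-12)
  # all-ones indicators are a no-op
  expect_equal(constrain_priors(st, matrix(1, n, 4))$p, st$p)
  # a voxel where only class 3 is admissible gets prior 1 there
  one <- matrix(0, 1, 4); one[3] <- 1
  got1 <- constrain_priors(prob_stack(matrix(0.25, 1, 4), paste0("c", 1:4),
                                      c(1, 1, 1)), one)
  expect_equal(unname(got1$p[1, ]), c(0, 0, 1, 0))
})

test_that("constrained priors vanish where indicators do, except fallbacks", {
  set.seed(6)
  n <- 6^3
  st <- random_stack(6, n, 3, c(6, 6, 6))
  ind <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
  got <- constrain_priors(st, ind)
  fallback <- rowSums(st$p * ind) == 0
  expect_equal(attr(got, "n_fallback"), sum(fallback))
  expect_true(all(got$p[!fallback, ][ind[!fallback, ] == 0] == 0))
  expect_equal(got$p[fallback, ], st$p[fallback, ])
})

test_that("enlarging a quantile interval never decreases an indicator", {
  ph <- small_phantom(n = 12, pn = 5, rf = 0, blur = 0, seed = 3)
  mask <- ph$labels$data > 0
  cfg <- ph$config
  bounds <- compute_bounds(ph$session, cfg, mask)
  wider <- as.data.frame(cfg)
  for (m in c("T1", "T2")) {
    wider[[paste0("q_lower.", m)]] <- pmax(0, wider[[paste0("q_lower.", m)]] - 0.2)
    wider[[paste0("q_upper.", m)]] <- pmin(1, wider[[paste0("q_upper.", m)]] + 0.2)
  }
  bounds_w <- compute_bounds(ph$session, emtseg:::validate_tissue_config(wider),
                             mask)
  ind <- indicator_stack(ph$session, bounds)
  ind_w <- indicator_stack(ph$session, bounds_w)
  expect_true(all(ind_w >= ind))
})

test_that("indicators are invariant to a global intensity rescaling", {
  ph <- small_phantom(n = 12, pn = 5, rf = 0, blur = 0, seed = 4)
  mask <- ph$labels$data > 0
  sess <- ph$session
  ind <- indicator_stack(sess, compute_bounds(sess, ph$config, mask))
  scaled <- session_from_matrix(sess, session_matrix(sess) * 3.7)
  ind_s <- indicator_stack(scaled, compute_bounds(scaled, ph$config, mask))
  expect_identical(ind, ind_s)
})
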