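# single-tissue config helper: one bias-eligible class (plus an optional
# ineligible one)
bias_test_config <- function(two_class = FALSE) {
  df <- data.frame(name = if (two_class) c("Wm", "Vb") else "Wm",
                   super_class = if (two_class) c("WM", "VB") else "WM",
                   weight = 1,
                   use_in_bias = if (two_class) c(TRUE, FALSE) else TRUE,
                   check.names = FALSE)
  df$`q_lower.T1` <- 0; df$`q_upper.T1` <- 1
  emtseg:::validate_tissue_config(df)
}

const_session <- function(arr) image_session(list(T1 = mri_volume(arr)))

test_that("zero residuals give an identically zero field", {
  d <- c(8, 8, 8)
  sess <- const_session(array(5, d))
  post <- prob_stack(matrix(1, prod(d), 1), "Wm", d)
  st <- mixture_state(matrix(5), list(matrix(0.01)), "Wm")
  bf <- estimate_bias(sess, st, post, bias_test_config(), order = 3L)
  expect_lt(max(abs(bf$fields$T1)), 1e-9)
})

test_that("a linear ramp is recovered exactly (vs the closed-form WLS oracle)", {
  d <- c(8, 8, 8)
  co <- emtseg:::unit_coords(d)
  ramp <- 0.4 * (2 * co$x - 1)
  arr <- 5 + ramp
  sess <- const_session(arr)
  n <- prod(d)
  post <- prob_stack(matrix(1, n, 1), "Wm", d)
  st <- mixture_state(matrix(mean(arr)), list(matrix(0.01)), "Wm")
  bf <- estimate_bias(sess, st, post, bias_test_config(), order = 1L)
  want <- as.numeric(ramp - mean(ramp))
  expect_lt(max(abs(bf$fields$T1 - want)), 1e-6)
  # closed-form weighted-least-squares oracle on the raw basis
  B <- poly_basis(d, 1L)
  r <- as.numeric(arr) - mean(arr)
  w <- rep(1 / 0.01, n)
  beta <- solve(t(B) %*% (w * B), t(B) %*% (w * r))
  oracle <- as.numeric(B %*% beta); oracle <- oracle - mean(oracle)
  expect_lt(max(abs(bf$fields$T1 - oracle)), 1e-8)
})

test_that("a constant offset is absorbed, not fitted", {
  d <- c(6, 6, 6)
  sess <- const_session(array(7, d))
  post <- prob_stack(matrix(1, prod(d), 1), "Wm", d)
  st <- mixture_state(matrix(5), list(matrix(0.01)), "Wm")  # resid = +2
  bf <- estimate_bias(sess, st, post, bias_test_config(), order = 2L)
  expect_lt(max(abs(bf$fields$T1)), 1e-9)
  # and correction preserves the mask mean (zero-mean field)
  corr <- correct_bias(sess, bf)
  expect_equal(mean(session_matrix(corr)), mean(session_matrix(sess)),
               tolerance = 1e-9)
})

test_that("increasing the basis order never increases the weighted RSS", {
  d <- c(8, 8, 8)
  set.seed(31)
  arr <- 5 + array(rnorm(prod(d), 0, 0.3), d) +
    0.5 * sin(pi * emtseg:::unit_coords(d)$x)
  sess <- const_session(arr)
  n <- prod(d)
  post <- prob_stack(matrix(1, n, 1), "Wm", d)
  st <- mixture_state(matrix(mean(arr)), list(matrix(0.09)), "Wm")
  r <- as.numeric(arr) - mean(arr)
  rss <- vapply(0:4, function(ord) {
    bf <- estimate_bias(sess, st, post, bias_test_config(), order = ord)
    sum((r - bf$fields$T1)^2)
  }, 0)
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("only bias-eligible tissues influence the fit (hard posteriors)", {
  d <- c(8, 8, 8)
  co <- emtseg:::unit_coords(d)
  wm_region <- co$x < 0.5
  arr <- ifelse(wm_region, 10, 50) + 0.6 * (2 * co$y - 1)
  sess <- const_session(array(arr, d))
  n <- prod(d)
  post <- prob_stack(cbind(as.numeric(wm_region), as.numeric(!wm_region)),
                     c("Wm", "Vb"), d)
  st <- mixture_state(matrix(c(10, 50), 2, 1),
                      list(matrix(0.04), matrix(0.04)), c("Wm", "Vb"))
  cfg <- bias_test_config(two_class = TRUE)
  bf_all <- estimate_bias(sess, st, post, cfg, order = 1L)
  post0 <- post; post0$p[, "Vb"] <- 0
  bf_zeroed <- estimate_bias(sess, st, post0, cfg, order = 1L)
  expect_lt(max(abs(bf_all$fields$T1 - bf_zeroed$fields$T1)), 1e-9)
  expect_error(estimate_bias(sess, st, post0,
                             emtseg:::validate_tissue_config(within(
                               as.data.frame(cfg), use_in_bias <- c(FALSE, FALSE))),
                             order = 1L),
               "use_in_bias")
})

test_that("working-space transform round-trips and linearizes a product", {
  d <- c(5, 5, 5)
  v <- mri_volume(array(seq(10, 200, length.out = prod(d)), d))
  w <- to_working_space(v)
  eps <- attr(w, "eps")
  back <- from_working_space(w, eps)
  expect_lt(max(abs(back$data - v$data)), 1e-12 * max(v$data))
  # multiplicative field becomes additive (up to the eps offset)
  f <- array(seq(0.8, 1.2, length.out = prod(d)), d)
  wf <- to_working_space(mri_volume(v$data * f), eps = eps)
  expect_equal(wf$data - w$data, log((v$data * f + eps) / (v$data + eps)),
               tolerance = 1e-12)
})

test_that("bias estimation is idempotent on a corrected noise-free session", {
  ph <- small_phantom(n = 16, pn = 0, rf = 20, blur = 0, seed = 8)
  mask <- ph$labels$data > 0
  ws <- lapply(session_fused(ph$session), to_working_space, mask = mask)
  wss <- image_session(lapply(ws, list))
  pri <- normalize_priors(ph$atlas)
  st <- initialize_state(wss, pri)
  em <- run_em(wss, st, pri, max_iter = 10)
  bf <- estimate_bias(wss, em$state, em$posteriors, ph$config, 4L, mask)
  corr <- correct_bias(wss, bf)
  em2 <- run_em(corr, em$state, pri, max_iter = 10)
  bf2 <- estimate_bias(corr, em2$state, em2$posteriors, ph$config, 4L, mask)
  scale_ws <- diff(range(session_matrix(wss)[mask, 1]))
  expect_lt(max(abs(bf2$fields$T1[mask])),
            0.05 * max(abs(bf$fields$T1[mask])) + 1e-3 * scale_ws)
})

test_that("the estimated log-space field tracks the true multiplicative bias", {
  ph <- small_phantom(n = 24, pn = 2, rf = 20, blur = 1, seed = 9)
  mask <- ph$labels$data > 0
  ws <- lapply(session_fused(ph$session), to_working_space, mask = mask)
  wss <- image_session(lapply(ws, list))
  pri <- normalize_priors(ph$atlas)
  em <- run_em(wss, initialize_state(wss, pri), pri, max_iter = 15)
  bf <- estimate_bias(wss, em$state, em$posteriors, ph$config, 4L, mask)
  expect_gt(cor(bf$fields$T1[mask], log(ph$fields$T1$data[mask])), 0.95)
})
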