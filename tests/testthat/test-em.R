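uni_session <- function(y) image_session(list(T1 = mri_volume(
  array(y, c(length(y), 1, 1)))))

test_that("e_step reproduces the hand-evaluated two-class posterior", {
  # y = 0.5 under N(0,1) and N(2,1), equal priors: exponent gap is 1
  sess <- uni_session(0.5)
  st <- mixture_state(matrix(c(0, 2), 2, 1), list(matrix(1), matrix(1)),
                      c("a", "b"))
  pri <- prob_stack(matrix(0.5, 1, 2), c("a", "b"), c(1, 1, 1))
  es <- e_step(sess, st, pri)
  expect_equal(unname(es$posteriors$p[1, ]),
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
})

test_that("zero prior forces zero posterior; flat likelihood returns the prior", {
  sess <- uni_session(c(0.3, 0.7))
  st <- mixture_state(matrix(c(0.5, 0.5), 2, 1),
                      list(matrix(1), matrix(1)), c("a", "b"))
  pri <- prob_stack(rbind(c(0, 1), c(0.3, 0.7)), c("a", "b"), c(2, 1, 1))
  es <- e_step(sess, st, pri)
  expect_equal(unname(es$posteriors$p[1, ]), c(0, 1))
  # identical class parameters -> posterior equals the prior exactly
  expect_equal(unname(es$posteriors$p[2, ]), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("m_step reproduces hand-computed weighted moments", {
  sess <- uni_session(c(1, 3))
  post <- prob_stack(rbind(c(0.75, 0.25), c(0.25, 0.75)), c("A", "B"),
                     c(2, 1, 1))
  st <- m_step(sess, post, reg = 0)
  expect_equal(unname(st$mu["A", ]), 1.5)
  expect_equal(unname(st$sigma[["A"]][1, 1]), 0.75)
  # hard posteriors -> plain per-class sample means
  sess2 <- uni_session(c(1, 2, 10, 14))
  hard <- prob_stack(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                     c("A", "B"), c(4, 1, 1))
  st2 <- m_step(sess2, hard, reg = 0)
  expect_equal(unname(st2$mu[, 1]), c(1.5, 12))
})

test_that("m_step is translation-equivariant and flags collapsed classes", {
  set.seed(1)
  y <- rnorm(50)
  sess <- uni_session(y)
  post <- prob_stack(cbind(runif(50, 0.2, 0.8), 0), c("A", "B"), c(50, 1, 1))
  post$p[, 2] <- 1 - post$p[, 1]
  st <- m_step(sess, post)
  st_shift <- m_step(uni_session(y + 5), post)
  expect_equal(st_shift$mu, st$mu + 5, tolerance = 1e-9)
  expect_equal(st_shift$sigma, st$sigma, tolerance = 1e-9)

  dead <- prob_stack(cbind(rep(1, 50), 0), c("A", "B"), c(50, 1, 1))
  expect_warning(st_d <- m_step(sess, dead, prev_state = st), "collapsed")
  expect_true(st_d$collapsed[2])
  expect_equal(st_d$mu["B", ], st$mu["B", ])
})

test_that("e_step/m_step match the naive per-voxel oracle to 1e-10", {
  set.seed(12)
  n <- 6^3
  Y <- cbind(rnorm(n, 10, 2), rnorm(n, 5, 1))
  colnames(Y) <- c("T1", "T2")
  sess <- image_session(list(T1 = mri_volume(array(Y[, 1], c(6, 6, 6))),
                             T2 = mri_volume(array(Y[, 2], c(6, 6, 6)))))
  mu <- rbind(c(9, 4.5), c(12, 6))
  sigma <- list(matrix(c(2, 0.3, 0.3, 1), 2), matrix(c(1.5, -0.2, -0.2, 0.8), 2))
  pri_p <- matrix(runif(n * 2), n, 2); pri_p <- pri_p / rowSums(pri_p)
  pri_p[1, ] <- c(0, 1)  # include a structural zero
  pri <- prob_stack(pri_p, c("a", "b"), c(6, 6, 6))
  st <- mixture_state(mu, sigma, c("a", "b"))
  es <- e_step(sess, st, pri)
  oracle <- naive_e_step(Y, mu, sigma, pri_p)
  expect_lt(max(abs(es$posteriors$p - oracle$post)), 1e-10)
  expect_equal(es$loglik, oracle$loglik, tolerance = 1e-10)

  ms <- m_step(sess, es$posteriors)
  oms <- naive_m_step(Y, es$posteriors$p)
  expect_lt(max(abs(ms$mu - oms$mu)), 1e-10)
  for (l in 1:2) expect_lt(max(abs(ms$sigma[[l]] - oms$sigma[[l]])), 1e-10)
})

test_that("initialize_state equals one naive m_step on the priors", {
  set.seed(13)
  n <- 5^3
  Y <- matrix(rnorm(n, 7, 2), n, 1, dimnames = list(NULL, "T1"))
  sess <- image_session(list(T1 = mri_volume(array(Y, c(5, 5, 5)))))
  p <- matrix(runif(n * 3), n, 3); p <- p / rowSums(p)
  pri <- prob_stack(p, c("a", "b", "c"), c(5, 5, 5))
  st <- initialize_state(sess, pri)
  oracle <- naive_m_step(Y, p)
  expect_lt(max(abs(st$mu - oracle$mu)), 1e-10)
  # one-hot priors on a noise-free phantom -> exact class means
  ph <- small_phantom(n = 12, pn = 0, rf = 0, blur = 0)
  st0 <- initialize_state(ph$session, normalize_priors(ph$atlas))
  means <- as.matrix(default_phantom_means())
  expect_equal(unname(st0$mu), unname(means), tolerance = 1e-9)
})

test_that("run_em converges, is monotone, and recovers mixture parameters", {
  set.seed(20)
  n <- 16^3
  truth_mu <- rbind(c(40, 180), c(140, 70))
  z <- rbinom(n, 1, 0.4) + 1
  Y <- truth_mu[z, ] + cbind(rnorm(n, 0, 8), rnorm(n, 0, 8))
  sess <- image_session(list(T1 = mri_volume(array(Y[, 1], c(16, 16, 16))),
                             T2 = mri_volume(array(Y[, 2], c(16, 16, 16)))))
  pri_p <- cbind(ifelse(z == 1, 0.7, 0.3), ifelse(z == 1, 0.3, 0.7))
  pri <- prob_stack(pri_p, c("a", "b"), c(16, 16, 16))
  st0 <- initialize_state(sess, pri)
  em <- run_em(sess, st0, pri, max_iter = 30, tol = 1e-7)
  expect_true(all(diff(em$trace) >= -1e-9 * abs(em$trace[-1])))
  expect_lt(max(abs(em$state$mu - truth_mu) / truth_mu), 0.02)
})

test_that("single-class EM lands on the global mean in one iteration", {
  set.seed(21)
  y <- rnorm(64, 3, 1)
  sess <- uni_session(y)
  pri <- prob_stack(matrix(1, 64, 1), "only", c(64, 1, 1))
  st0 <- initialize_state(sess, pri)
  em <- run_em(sess, st0, pri, max_iter = 5)
  expect_equal(unname(em$state$mu[1, 1]), mean(y), tolerance = 1e-9)
  expect_lte(length(em$trace), 2)
})
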