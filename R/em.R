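# Multi-modal Gaussian-mixture EM engine.
#
# The model: voxel intensity vectors y_i (one component per modality) are
# Gaussian per tissue class with full inter-modality covariance; the class
# probability p(class l at voxel i) is supplied entirely by the (warped,
# weighted, context-constrained) spatial prior — there are no free global
# mixing weights.  The E-step turns densities x priors into per-voxel
# posteriors (in log space); the M-step re-estimates each class's mean
# vector and covariance from the posterior-weighted data.

#' Mixture state: per-class multi-modal Gaussian parameters
#'
#' @param mu K x M matrix of class mean vectors (rows = classes).
#' @param sigma list of K symmetric positive-definite M x M covariances.
#' @param classes class names.
#' @param collapsed logical vector flagging classes whose posterior mass
#'   vanished (their parameters are frozen).
#' @export
mixture_state <- function(mu, sigma, classes, collapsed = NULL) {
  mu <- as.matrix(mu)
  stopifnot(nrow(mu) == length(classes), length(sigma) == length(classes),
            all(is.finite(mu)))
  if (is.null(collapsed)) collapsed <- rep(FALSE, length(classes))
  rownames(mu) <- names(sigma) <- classes
  structure(list(mu = mu, sigma = sigma, classes = classes,
                 collapsed = collapsed),
            class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("<mixture_state> %d classes x %d modalities\n",
              length(x$classes), ncol(x$mu)))
  print(round(x$mu, 4))
  invisible(x)
}

# per-class multivariate normal log-density of all rows of Y
class_log_density <- function(Y, mu_l, sigma_l, class_name = "?") {
  M <- ncol(Y)
  U <- tryCatch(chol(sigma_l), error = function(e) NULL)
  if (is.null(U))
    stop("singular covariance for class ", class_name)
  Yc <- sweep(Y, 2L, mu_l)
  A <- Yc %*% backsolve(U, diag(M))
  maha <- rowSums(A * A)
  -0.5 * (M * log(2 * pi) + 2 * sum(log(diag(U))) + maha)
}

#' E-step: per-voxel class posteriors and total log-likelihood
#'
#' Posterior of class l at voxel i is proportional to the multivariate
#' normal density of the (bias-corrected) intensity vector under the class
#' parameters times the per-voxel prior, renormalized per voxel; computed
#' in log space for stability.  A zero prior forces a zero posterior
#' regardless of likelihood.  The returned log-likelihood is
#' `sum_i log sum_l N(y_i; mu_l, Sigma_l) p(class l at i)`.
#'
#' @param session corrected fused [image_session()].
#' @param state a [mixture_state()].
#' @param priors prior [prob_stack()] on the session grid.
#' @return `list(posteriors = prob_stack, loglik = numeric)`.
#' @export
e_step <- function(session, state, priors) {
  Y <- session_matrix(session)
  stopifnot(nrow(Y) == nrow(priors$p),
            length(state$classes) == length(priors$classes))
  K <- length(state$classes)
  logp <- matrix(-Inf, nrow(Y), K)
  lp_prior <- log(priors$p)
  for (l in seq_len(K)) {
    has <- priors$p[, l] > 0
    if (!any(has)) next
    ld <- class_log_density(Y[has, , drop = FALSE], state$mu[l, ],
                            state$sigma[[l]], state$classes[l])
    logp[has, l] <- ld + lp_prior[has, l]
  }
  lse <- row_logsumexp(logp)
  # voxels where every class density underflows: fall back to the prior
  dead <- !is.finite(lse)
  post <- exp(logp - ifelse(dead, 0, lse))
  if (any(dead)) post[dead, ] <- priors$p[dead, , drop = FALSE]
  loglik <- sum(lse[!dead])
  list(posteriors = prob_stack(post, priors$classes, priors$dim,
                               priors$spacing, priors$origin),
       loglik = loglik)
}

#' M-step: posterior-weighted Gaussian parameter updates
#'
#' Class means are posterior-weighted means of the corrected intensities;
#' covariances are posterior-weighted scatter matrices, regularized by
#' `reg x mean(per-modality variance) x I` to stay positive-definite.
#' A class whose posterior mass falls at or below `mass_eps` is flagged
#' collapsed: its previous parameters are retained (or global statistics
#' when there is no previous state) and a warning is emitted, keeping the
#' class vector shape stable.
#'
#' @param session corrected fused [image_session()].
#' @param posteriors a [prob_stack()] of responsibilities.
#' @param prev_state previous [mixture_state()] for collapsed classes.
#' @param reg covariance ridge factor (default `1e-6`; `0` disables).
#' @param mass_eps minimum class mass.
#' @return a [mixture_state()].
#' @export
m_step <- function(session, posteriors, prev_state = NULL, reg = 1e-6,
                   mass_eps = 1e-8) {
  Y <- session_matrix(session)
  P <- posteriors$p
  stopifnot(nrow(Y) == nrow(P))
  M <- ncol(Y)
  K <- ncol(P)
  delta <- reg * mean(apply(Y, 2L, stats::var))
  if (!is.finite(delta)) delta <- 0
  glob_mu <- colMeans(Y)
  glob_sig <- stats::cov(Y) + max(delta, 1e-12) * diag(M)
  mu <- matrix(NA_real_, K, M)
  sigma <- vector("list", K)
  collapsed <- rep(FALSE, K)
  for (l in seq_len(K)) {
    mass <- sum(P[, l])
    if (mass <= mass_eps) {
      collapsed[l] <- TRUE
      if (!is.null(prev_state)) {
        mu[l, ] <- prev_state$mu[l, ]
        sigma[[l]] <- prev_state$sigma[[l]]
      } else {
        mu[l, ] <- glob_mu
        sigma[[l]] <- glob_sig
      }
      warning("class ", posteriors$classes[l],
              " collapsed (posterior mass ", signif(mass, 3),
              "); parameters retained", call. = FALSE)
      next
    }
    mu[l, ] <- colSums(P[, l] * Y) / mass
    Yc <- sweep(Y, 2L, mu[l, ])
    S <- crossprod(Yc, P[, l] * Yc) / mass
    sigma[[l]] <- (S + t(S)) / 2 + delta * diag(M)
  }
  colnames(mu) <- colnames(Y)
  sigma <- lapply(sigma, function(s) {
    dimnames(s) <- list(colnames(Y), colnames(Y)); s
  })
  mixture_state(mu, sigma, posteriors$classes, collapsed)
}

#' Initialize mixture parameters from (constrained) priors
#'
#' One M-step treating the prior stack as responsibilities: with
#' informative, context-constrained priors this yields robust initial
#' tissue statistics without any intensity clustering.
#'
#' @param session corrected fused [image_session()].
#' @param priors prior [prob_stack()].
#' @inheritParams m_step
#' @export
initialize_state <- function(session, priors, reg = 1e-6) {
  m_step(session, priors, prev_state = NULL, reg = reg)
}

#' Run EM to convergence
#'
#' Alternates [e_step()] and [m_step()] with the prior stack held fixed
#' until the relative log-likelihood change drops below `tol` or
#' `max_iter` iterations are reached.  With priors and bias fixed the
#' log-likelihood trace is non-decreasing (EM monotonicity).
#'
#' @param session corrected fused [image_session()].
#' @param state initial [mixture_state()] (e.g. [initialize_state()]).
#' @param priors prior [prob_stack()], fixed during the run.
#' @param max_iter iteration cap (default 30).
#' @param tol relative log-likelihood tolerance (default 1e-5).
#' @inheritParams m_step
#' @return `list(state, posteriors, trace)` where `trace` is the vector of
#'   log-likelihoods (one per E-step performed).
#' @export
run_em <- function(session, state, priors, max_iter = 30L, tol = 1e-5,
                   reg = 1e-6) {
  trace <- numeric(0)
  es <- NULL
  for (it in seq_len(max_iter)) {
    es <- e_step(session, state, priors)
    trace <- c(trace, es$loglik)
    if (it > 1L) {
      rel <- abs(es$loglik - trace[it - 1L]) /
        max(abs(trace[it - 1L]), .Machine$double.eps)
      if (rel < tol) break
    }
    state <- m_step(session, es$posteriors, prev_state = state, reg = reg)
  }
  list(state = state, posteriors = es$posteriors, trace = trace)
}

#' Posterior-weighted per-class mean intensities
#'
#' Convenience for recovery checks: the posterior-weighted mean intensity
#' vector of each class on a (corrected, linear-space) session.
#'
#' @param session fused [image_session()].
#' @param posteriors a [prob_stack()].
#' @return K x M matrix.
#' @export
class_means <- function(session, posteriors) {
  Y <- session_matrix(session)
  P <- posteriors$p
  mass <- colSums(P)
  out <- crossprod(P, Y) / ifelse(mass > 0, mass, NA_real_)
  rownames(out) <- posteriors$classes
  out
}
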