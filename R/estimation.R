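# Model fitting.
#
# fit_snlls() iterates only over the directed parameters, minimizing the
# reduced (variable-projection) objective with its analytic gradient,
# then recovers the undirected and mean parameters by one weighted
# linear solve.  fit_full_ls() minimizes the same discrepancy over the
# full parameter vector and serves as the baseline for equivalence and
# iteration-count comparisons.  Both use the same quasi-Newton optimizer
# (stats::nlminb) so that iteration counts are comparable.
#
# Convergence bookkeeping: a fit is flagged converged when the objective
# is finite and either the optimizer stopped on its relative-change test
# (relative objective change below 1e-12 by default) or the sup-norm of
# the gradient at the solution is below the gradient tolerance.
# Non-convergence is a recorded outcome, not an exception.  Variance
# positivity is not enforced in the linear solve -- the estimator is
# unconstrained -- so negative variance estimates are reported with a
# warning.

default_control <- function(control) {
  ctl <- list(iter_max = 500L, eval_max = 1000L, rel_tol = 1e-12,
              grad_tol = 1e-6, warn_negative_variance = TRUE)
  ctl[names(control)] <- control
  ctl
}

new_fit <- function(model, method, weight_kind, tl, tw, objective,
                    iterations, converged, gradient_norm, message = "") {
  nl <- length(model$par_lambda); no <- length(model$par_omega)
  ng <- length(model$par_gamma)
  theta_omega <- stats::setNames(tw[seq_len(no)], model$par_omega)
  theta_gamma <- stats::setNames(tw[no + seq_len(ng)], model$par_gamma)
  structure(list(
    model = model, method = method, weight = weight_kind,
    theta_lambda = stats::setNames(tl, model$par_lambda),
    theta_omega = theta_omega, theta_gamma = theta_gamma,
    theta = c(stats::setNames(tl, model$par_lambda), theta_omega, theta_gamma),
    objective = objective, iterations = iterations,
    converged = converged, gradient_norm = gradient_norm,
    message = message),
    class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (%s weight): objective %.6g, %d iteration%s, %s\n",
              toupper(gsub("_", " ", x$method)), x$weight, x$objective,
              x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  gradient sup-norm: %.3g\n", x$gradient_norm))
  print(round(x$theta, digits))
  invisible(x)
}

# resolve data / (S, N, means) input into the observed moment vector and
# the pieces needed for the weight matrix
resolve_moments <- function(model, data, S, N, means, denominator = "N") {
  if (!is.null(data)) {
    sm <- sample_moments(data, denominator)
    S <- sm$S; N <- sm$N; means <- sm$means
  }
  if (is.null(S))
    stop_snllsem("supply either raw data or a sample covariance matrix S",
                 "snllsem_data_error")
  if (!is_symmetric_num(S))
    stop_snllsem("sample covariance S is not symmetric", "snllsem_data_error")
  if (nrow(S) != model$m_obs)
    stop_snllsem(sprintf("S is %d x %d but the model has %d observed variables",
                         nrow(S), ncol(S), model$m_obs), "snllsem_dim_error")
  has_mean <- nrow(model$gamma) > 0L
  if (has_mean && is.null(means))
    stop_snllsem("the model has a mean structure: supply raw data or sample means",
                 "snllsem_data_error")
  s <- vech(S)
  if (has_mean) s <- c(s, means)
  list(S = S, N = N, means = means, s = s, has_mean = has_mean)
}

resolve_weight <- function(weight, S, m_obs, stacked) {
  if (inherits(weight, "snlls_weight")) return(weight)
  if (is.matrix(weight))
    return(weight_matrix("user", S = S, m_obs = m_obs, stacked = stacked,
                         V = weight))
  weight_matrix(match.arg(weight, c("gls", "uls")), S = S, m_obs = m_obs,
                stacked = stacked)
}

check_variances <- function(model, theta_omega, warn) {
  if (!warn || !length(theta_omega)) return(invisible())
  diag_labels <- unique(model$omega$label[
    model$omega$i == model$omega$j & !is.na(model$omega$label)])
  neg <- theta_omega[names(theta_omega) %in% diag_labels & theta_omega < 0]
  if (length(neg))
    warning(sprintf("negative variance estimate(s): %s",
                    paste(sprintf("%s = %.4g", names(neg), neg), collapse = ", ")),
            call. = FALSE)
  invisible()
}

#' Default starting values for the directed parameters
#'
#' Only the directed parameters need starting values under variable
#' projection.  The deterministic default is 0.5 for every free directed
#' parameter, overridable per label; it is a simple stand-in for
#' regression-based loading starts.
#'
#' @param model a \code{ram_model}.
#' @param S sample covariance (unused by the default rule; kept in the
#'   signature for data-dependent overrides).
#' @param override named numeric vector replacing the default for the
#'   named labels.
#' @return named numeric vector over \code{model$par_lambda}.
#' @export
starting_values <- function(model, S = NULL, override = NULL) {
  st <- stats::setNames(rep(0.5, length(model$par_lambda)), model$par_lambda)
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(st))
    if (length(bad))
      stop_snllsem(sprintf("unknown directed parameter '%s' in start override", bad[1]),
                   "snllsem_label_error")
    st[names(override)] <- override
  }
  st
}

# shared quasi-Newton driver; obj/grad operate on the free vector
run_nlminb <- function(start, obj, grad, ctl) {
  res <- tryCatch(
    stats::nlminb(start, objective = obj, gradient = grad,
                  control = list(iter.max = ctl$iter_max,
                                 eval.max = ctl$eval_max,
                                 rel.tol = ctl$rel_tol)),
    error = function(e) NULL)
  if (is.null(res))
    return(list(par = start, objective = NA_real_, iterations = NA_integer_,
                ok = FALSE, message = "optimizer error"))
  list(par = res$par, objective = res$objective,
       iterations = res$iterations, ok = res$convergence == 0,
       message = res$message)
}

guarded <- function(f, fallback) {
  function(x) tryCatch(f(x), snllsem_singular = function(e) fallback,
                       snllsem_nonfinite = function(e) fallback)
}

#' Fit a model by separable nonlinear least squares
#'
#' Minimizes the reduced least squares objective over the directed
#' parameters only (quasi-Newton with the analytic reduced gradient),
#' then recovers the undirected and mean parameters jointly by a single
#' weighted linear solve at the optimum.  Models without free directed
#' parameters skip optimization entirely: the whole estimate is the
#' closed-form linear solve, reported with 0 iterations.
#'
#' The point estimates coincide with those of \code{\link{fit_full_ls}}
#' under the same weight matrix; only the optimization path differs.
#'
#' @param model a \code{ram_model}.
#' @param data raw data (rows = cases, columns = observed variables); or
#'   supply \code{S}, \code{N} (and \code{means}) instead.
#' @param S sample covariance matrix.
#' @param N sample size (used only for bookkeeping here).
#' @param means sample means (required by models with a mean structure
#'   when \code{data} is not given).
#' @param weight \code{"gls"}, \code{"uls"}, a weight matrix, or an
#'   \code{snlls_weight}.
#' @param start optional named override of the directed starting values.
#' @param control list of optimizer settings: \code{iter_max} (500),
#'   \code{eval_max} (1000), \code{rel_tol} (1e-12), \code{grad_tol}
#'   (1e-6), \code{warn_negative_variance} (TRUE).
#' @param denominator covariance denominator when \code{data} is given,
#'   \code{"N"} (default) or \code{"N-1"}.
#' @return an object of class \code{sem_fit}.
#' @export
fit_snlls <- function(model, data = NULL, S = NULL, N = NULL, means = NULL,
                      weight = "gls", start = NULL, control = list(),
                      denominator = "N") {
  ctl <- default_control(control)
  mom <- resolve_moments(model, data, S, N, means, denominator)
  W <- resolve_weight(weight, mom$S, model$m_obs, mom$has_mean)
  ctx <- model_context(model)
  s <- mom$s; Vm <- W$V

  eval_at <- function(tl) {
    B <- safe_binv(fill_lambda(model, tl))
    st <- stack_G(ctx, build_G_ctx(ctx, B))
    sh <- s - st$offset
    VG <- Vm %*% st$G
    w <- pinv_solve(crossprod(st$G, VG), drop(crossprod(VG, sh)))
    r <- sh - drop(st$G %*% w)
    list(B = B, st = st, w = w, r = r, f = drop(crossprod(r, Vm %*% r)))
  }
  grad_at <- function(tl, ev) {
    vr <- drop(Vm %*% ev$r)
    dBs <- dB_list(ctx, ev$B)
    vapply(seq_len(ctx$n_lam), function(n) {
      dg <- dG_ctx_n(ctx, ev$B, dBs[[n]])
      -2 * sum(vr * (drop(dg$dG %*% ev$w) + dg$doffset))
    }, numeric(1))
  }

  if (ctx$n_lam == 0L) {
    ev <- eval_at(numeric(0))
    fit <- new_fit(model, "snlls", W$kind, numeric(0), ev$w, ev$f,
                   0L, TRUE, 0, "closed form (no directed parameters)")
    check_variances(model, fit$theta_omega, ctl$warn_negative_variance)
    return(fit)
  }

  tl0 <- starting_values(model, mom$S, start)
  eval_at(tl0)   # singular I - Lambda at the start is an immediate error
  obj <- guarded(function(tl) eval_at(tl)$f, 1e35)
  grd <- guarded(function(tl) { ev <- eval_at(tl); grad_at(tl, ev) },
                 numeric(length(tl0)))
  res <- run_nlminb(tl0, obj, grd, ctl)

  tl <- res$par
  ev <- tryCatch(eval_at(tl), snllsem_singular = function(e) NULL)
  if (is.null(ev)) {
    fit <- new_fit(model, "snlls", W$kind, tl, rep(NA_real_, ctx$n_om + ctx$n_gam),
                   NA_real_, res$iterations %||% NA_integer_, FALSE, Inf,
                   "singular I - Lambda at the solution")
    return(fit)
  }
  g <- grad_at(tl, ev)
  gnorm <- if (length(g)) max(abs(g)) else 0
  converged <- is.finite(ev$f) && (res$ok || gnorm <= ctl$grad_tol)
  fit <- new_fit(model, "snlls", W$kind, tl, ev$w, ev$f,
                 res$iterations, converged, gnorm, res$message)
  check_variances(model, fit$theta_omega, ctl$warn_negative_variance)
  fit
}

#' Fit a model by full least squares
#'
#' Minimizes the least squares discrepancy \code{(s - sigma(theta))^T V
#' (s - sigma(theta))} over the full parameter vector by the same
#' quasi-Newton optimizer used by \code{\link{fit_snlls}}, with the
#' analytic gradient assembled from the linearity of the implied moments
#' in the undirected/mean parameters and the Jacobian of G.  Starting
#' values: directed parameters as in \code{\link{starting_values}};
#' free variances start at the matching sample variance (0.05 for latent
#' variables), covariances at 0, means at the sample mean (0 for latent
#' positions).
#'
#' @inheritParams fit_snlls
#' @param start optional named override of any free parameter's start.
#' @return an object of class \code{sem_fit}.
#' @export
fit_full_ls <- function(model, data = NULL, S = NULL, N = NULL, means = NULL,
                        weight = "gls", start = NULL, control = list(),
                        denominator = "N") {
  ctl <- default_control(control)
  mom <- resolve_moments(model, data, S, N, means, denominator)
  W <- resolve_weight(weight, mom$S, model$m_obs, mom$has_mean)
  ctx <- model_context(model)
  s <- mom$s; Vm <- W$V
  nl <- ctx$n_lam; no <- ctx$n_om; ng <- ctx$n_gam

  # simple deterministic starts for the linear block
  tw0 <- numeric(no + ng)
  for (k in seq_len(no)) {
    pos <- ctx$im$C[[k]][1, ]
    tw0[k] <- if (pos[1] != pos[2]) 0
    else if (pos[1] <= ctx$m_obs) mom$S[pos[1], pos[1]] else 0.05
  }
  for (k in seq_len(ng)) {
    a <- ctx$im$A[[k]][1]
    tw0[no + k] <- if (a <= ctx$m_obs && !is.null(mom$means)) mom$means[a] else 0
  }
  th0 <- c(starting_values(model, mom$S), tw0)
  names(th0) <- theta_names(model)
  if (!is.null(start)) {
    bad <- setdiff(names(start), names(th0))
    if (length(bad))
      stop_snllsem(sprintf("unknown parameter '%s' in start override", bad[1]),
                   "snllsem_label_error")
    th0[names(start)] <- start
  }

  eval_at <- function(th) {
    tl <- th[seq_len(nl)]; tw <- th[nl + seq_len(no + ng)]
    B <- safe_binv(fill_lambda(model, tl))
    st <- stack_G(ctx, build_G_ctx(ctx, B))
    r <- s - (drop(st$G %*% tw) + st$offset)
    list(B = B, st = st, tw = tw, r = r, f = drop(crossprod(r, Vm %*% r)))
  }
  grad_at <- function(th, ev) {
    vr <- drop(Vm %*% ev$r)
    gl <- if (nl) {
      dBs <- dB_list(ctx, ev$B)
      vapply(seq_len(nl), function(n) {
        dg <- dG_ctx_n(ctx, ev$B, dBs[[n]])
        -2 * sum(vr * (drop(dg$dG %*% ev$tw) + dg$doffset))
      }, numeric(1))
    } else numeric(0)
    c(gl, -2 * drop(crossprod(ev$st$G, vr)))
  }

  eval_at(th0)
  obj <- guarded(function(th) eval_at(th)$f, 1e35)
  grd <- guarded(function(th) { ev <- eval_at(th); grad_at(th, ev) },
                 numeric(length(th0)))
  res <- run_nlminb(th0, obj, grd, ctl)

  th <- res$par
  ev <- tryCatch(eval_at(th), snllsem_singular = function(e) NULL)
  if (is.null(ev))
    return(new_fit(model, "full_ls", W$kind, th[seq_len(nl)],
                   rep(NA_real_, no + ng), NA_real_,
                   res$iterations %||% NA_integer_, FALSE, Inf,
                   "singular I - Lambda at the solution"))
  g <- grad_at(th, ev)
  gnorm <- if (length(g)) max(abs(g)) else 0
  converged <- is.finite(ev$f) && (res$ok || gnorm <= ctl$grad_tol)
  fit <- new_fit(model, "full_ls", W$kind, th[seq_len(nl)], ev$tw, ev$f,
                 res$iterations, converged, gnorm, res$message)
  check_variances(model, fit$theta_omega, ctl$warn_negative_variance)
  fit
}

#' Iteratively reweighted least squares towards maximum likelihood
#'
#' Alternates an SNLLS fit with a weight update \code{V = 1/2 D^T
#' (Sigma^-1 x Sigma^-1) D} evaluated at the current implied covariance,
#' starting from the sample covariance (so the first pass is exactly the
#' GLS fit), until \code{max |Sigma_t - Sigma_(t-1)| < outer_tol} or
#' \code{max_outer} sweeps.  At the fixed point the weight is the ML
#' weight, so the estimates solve the normal-theory likelihood
#' equations; for a saturated model the implied covariance reproduces S
#' exactly after the first sweep.
#'
#' @inheritParams fit_snlls
#' @param control adds \code{outer_tol} (1e-6) and \code{max_outer} (50)
#'   to the \code{\link{fit_snlls}} settings.
#' @return an \code{sem_fit} with \code{method = "irls_ml"} and an extra
#'   \code{outer_iterations} field; \code{iterations} accumulates the
#'   inner optimizer iterations.
#' @export
irls_ml <- function(model, data = NULL, S = NULL, N = NULL, means = NULL,
                    start = NULL, control = list(), denominator = "N") {
  ctl <- default_control(control)
  outer_tol <- ctl$outer_tol %||% 1e-6
  max_outer <- ctl$max_outer %||% 50L
  mom <- resolve_moments(model, data, S, N, means, denominator)

  Sigma_prev <- mom$S
  fit <- NULL; total_iter <- 0L; outer <- 0L; converged_outer <- FALSE
  while (outer < max_outer) {
    outer <- outer + 1L
    if (min(eigen(Sigma_prev, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop_snllsem(sprintf(
        "implied covariance became indefinite at outer iteration %d", outer),
        "snllsem_indefinite")
    W <- weight_matrix("gls", S = Sigma_prev, stacked = mom$has_mean)
    fit <- fit_snlls(model, S = mom$S, N = mom$N, means = mom$means,
                     weight = W, start = start,
                     control = ctl[c("iter_max", "eval_max", "rel_tol",
                                     "grad_tol", "warn_negative_variance")])
    total_iter <- total_iter + fit$iterations
    Sigma_t <- implied_sigma(model, fit$theta)
    delta <- max(abs(Sigma_t - Sigma_prev))
    Sigma_prev <- Sigma_t
    if (delta < outer_tol) { converged_outer <- TRUE; break }
  }
  fit$method <- "irls_ml"
  fit$iterations <- total_iter
  fit$outer_iterations <- outer
  fit$converged <- fit$converged && converged_outer
  if (!converged_outer)
    fit$message <- sprintf("outer loop did not converge in %d sweeps", max_outer)
  fit
}
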