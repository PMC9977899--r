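# Multivariate-normal data generation from a model's implied moments,
# the three built-in fixture models, and the convergence simulation
# comparing SNLLS with the full GLS optimization on small samples.

#' Simulate data from a model's implied moments
#'
#' Draws \code{N} i.i.d. multivariate-normal rows with mean
#' \code{mu(theta0)} (zero for models without a mean structure) and
#' covariance \code{Sigma(theta0)}.  Reproducible per seed.
#'
#' @param model a \code{ram_model}.
#' @param theta0 numeric parameter vector (the population values).
#' @param N number of rows.
#' @param seed optional integer seed (set locally; the caller's RNG
#'   state is restored on exit).
#' @return numeric \code{N x m_obs} matrix with the observed variable
#'   names as columns.
#' @export
simulate_data <- function(model, theta0, N, seed = NULL) {
  stopifnot(N >= 1)
  Sigma <- implied_sigma(model, theta0)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_snllsem("implied covariance at theta0 is not positive definite",
                 "snllsem_indefinite")
  mu <- implied_mu(model, theta0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  X <- MASS::mvrnorm(N, mu = mu, Sigma = Sigma)
  if (N == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- model$nodes[seq_len(model$m_obs)]
  X
}

#' Built-in fixture models
#'
#' Three small structural equation models used throughout the package's
#' tests and the convergence study, each returned with population
#' parameter values:
#' \describe{
#'   \item{\code{fig2_model()}}{two latent factors with three indicators
#'     each (first loading per factor fixed at 1 for identification),
#'     a structural path between the factors, and eight free error
#'     variances.  Population values: free loadings 0.8 and 0.6 per
#'     factor, structural path 0.25, all variances 1 -- a deliberately
#'     weak-loading regime in which small-sample non-convergence is
#'     common.}
#'   \item{\code{fig5_model()}}{one latent variable measured by two
#'     indicators with both loadings fixed at 1 and all three variances
#'     free: no free directed parameters, so the least squares estimate
#'     is closed-form.}
#'   \item{\code{fig1_model()}}{a bi-factor structure: a general factor
#'     loading on six indicators, two correlated specific factors with
#'     three indicators each, and free error variances -- the worked
#'     example for the trek rules.}
#' }
#'
#' @return list with components \code{model} (a \code{ram_model}) and
#'   \code{theta0} (named population parameter vector).
#' @export
fig2_model <- function() {
  model <- parse_model("
    latent: zeta1 zeta2
    zeta1 -> x1 = 1
    zeta1 -> x2 lambda2
    zeta1 -> x3 lambda3
    zeta2 -> x4 = 1
    zeta2 -> x5 lambda5
    zeta2 -> x6 lambda6
    zeta1 -> zeta2 beta
    x1 <-> x1 omega1
    x2 <-> x2 omega2
    x3 <-> x3 omega3
    x4 <-> x4 omega4
    x5 <-> x5 omega5
    x6 <-> x6 omega6
    zeta1 <-> zeta1 omega_zeta1
    zeta2 <-> zeta2 omega_zeta2")
  theta0 <- c(lambda2 = 0.8, lambda3 = 0.6, lambda5 = 0.8, lambda6 = 0.6,
              beta = 0.25,
              omega1 = 1, omega2 = 1, omega3 = 1, omega4 = 1, omega5 = 1,
              omega6 = 1, omega_zeta1 = 1, omega_zeta2 = 1)
  list(model = model, theta0 = theta0[theta_names(model)])
}

#' @rdname fig2_model
#' @export
fig5_model <- function() {
  model <- parse_model("
    latent: l
    l -> x1 = 1
    l -> x2 = 1
    x1 <-> x1 omega1
    x2 <-> x2 omega2
    l  <-> l  omega_l")
  theta0 <- c(omega1 = 1, omega2 = 1, omega_l = 1)
  list(model = model, theta0 = theta0[theta_names(model)])
}

#' @rdname fig2_model
#' @export
fig1_model <- function() {
  model <- parse_model("
    latent: zeta1 zeta2 G
    zeta1 -> X1 lambda1
    zeta1 -> X2 lambda2
    zeta1 -> X3 lambda3
    zeta2 -> X4 lambda4
    zeta2 -> X5 lambda5
    zeta2 -> X6 lambda6
    G -> X1 beta1
    G -> X2 beta2
    G -> X3 beta3
    G -> X4 beta4
    G -> X5 beta5
    G -> X6 beta6
    X1 <-> X1 omega_1
    X2 <-> X2 omega_2
    X3 <-> X3 omega_3
    X4 <-> X4 omega_4
    X5 <-> X5 omega_5
    X6 <-> X6 omega_6
    zeta1 <-> zeta1 omega_zeta1
    zeta2 <-> zeta2 omega_zeta2
    G <-> G omega_G
    zeta1 <-> zeta2 omega_l")
  theta0 <- c(stats::setNames(rep(0.7, 6), paste0("lambda", 1:6)),
              stats::setNames(rep(0.4, 6), paste0("beta", 1:6)),
              stats::setNames(rep(1, 6), paste0("omega_", 1:6)),
              omega_zeta1 = 1, omega_zeta2 = 1, omega_G = 1, omega_l = 0.3)
  list(model = model, theta0 = theta0[theta_names(model)])
}

# deterministic per-replication seed below 2^31
study_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx * 9973) %% 2147483629)
}

#' Convergence simulation: SNLLS versus full GLS optimization
#'
#' For each sample size in \code{N_grid}, draws \code{reps} datasets
#' from the \code{\link{fig2_model}} population (or another supplied
#' model), and fits the true model to every dataset with the GLS weight
#' by both the reduced (SNLLS) and the full least squares optimization.
#' Both methods consume the identical dataset and the identical weight
#' matrix per replication.  A replication is recorded as non-converged
#' when the fit errors (e.g. a singular sample covariance), the
#' optimizer fails, or the convergence test is not met at the iteration
#' cap; failures are recorded, never raised.
#'
#' @param reps replications per sample size.
#' @param N_grid vector of sample sizes.
#' @param seed integer master seed; replication seeds derive from it
#'   deterministically.
#' @param methods subset of \code{c("snlls", "full_gls")}.
#' @param model,theta0 population model and values (default
#'   \code{\link{fig2_model}}).
#' @param out_csv optional path: write the per-replication records as
#'   CSV.
#' @return an object of class \code{convergence_study}: list with
#'   \code{records} (one row per fit: \code{N}, \code{rep},
#'   \code{seed}, \code{data_checksum}, \code{method},
#'   \code{converged}, \code{iterations}, \code{objective},
#'   \code{beta_hat}) and \code{summary} (per \code{N} and method:
#'   \code{n_converged}, \code{median_iterations} among converged
#'   fits).
#' @export
convergence_study <- function(reps = 200, N_grid = seq(10, 100, by = 10),
                              seed = 1, methods = c("snlls", "full_gls"),
                              model = NULL, theta0 = NULL, out_csv = NULL) {
  stopifnot(reps >= 1)
  methods <- match.arg(methods, c("snlls", "full_gls"), several.ok = TRUE)
  if (is.null(model)) {
    fx <- fig2_model(); model <- fx$model; theta0 <- fx$theta0
  }
  beta_lab <- if ("beta" %in% model$par_lambda) "beta" else NA_character_

  rows <- list()
  idx <- 0L
  for (N in N_grid) for (rp in seq_len(reps)) {
    idx <- idx + 1L
    rseed <- study_seed(seed, idx)
    dat <- simulate_data(model, theta0, N, seed = rseed)
    checksum <- signif(sum(dat) + sum(dat^2), 12)
    S <- sample_moments(dat)$S
    W <- tryCatch(weight_matrix("gls", S = S), snllsem_error = function(e) NULL)
    for (meth in methods) {
      fit <- if (is.null(W)) NULL else tryCatch(
        suppressWarnings(
          if (meth == "snlls") fit_snlls(model, S = S, N = N, weight = W)
          else fit_full_ls(model, S = S, N = N, weight = W)),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, rep = rp, seed = rseed, data_checksum = checksum,
        method = meth,
        converged = !is.null(fit) && isTRUE(fit$converged),
        iterations = if (is.null(fit)) NA_integer_ else fit$iterations,
        objective = if (is.null(fit)) NA_real_ else fit$objective,
        beta_hat = if (is.null(fit) || is.na(beta_lab)) NA_real_
                   else unname(fit$theta_lambda[beta_lab]))
    }
  }
  records <- do.call(rbind, rows)

  agg <- lapply(split(records, list(records$N, records$method), drop = TRUE),
                function(d) data.frame(
                  N = d$N[1], method = d$method[1],
                  n_converged = sum(d$converged),
                  median_iterations = stats::median(d$iterations[d$converged])))
  summary <- do.call(rbind, agg)
  summary <- summary[order(summary$N, summary$method), ]
  rownames(summary) <- NULL

  if (!is.null(out_csv))
    utils::write.csv(records, out_csv, row.names = FALSE)
  structure(list(records = records, summary = summary,
                 reps = reps, N_grid = N_grid, seed = seed),
            class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat(sprintf("convergence study: %d replications per N, master seed %d\n",
              x$reps, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot a convergence study
#'
#' Converged counts and median iterations by sample size, one line per
#' method (requires ggplot2).
#'
#' @param x a \code{convergence_study}.
#' @param which \code{"converged"} or \code{"iterations"}.
#' @param ... unused.
#' @export
plot.convergence_study <- function(x, which = c("converged", "iterations"), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_snllsem("plotting requires ggplot2", "snllsem_plot_error")
  which <- match.arg(which)
  d <- x$summary
  yvar <- if (which == "converged") "n_converged" else "median_iterations"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$N, y = .data[[yvar]],
                                  colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "sample size N",
                  y = if (which == "converged") "converged replications"
                      else "median iterations (converged fits)")
}
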