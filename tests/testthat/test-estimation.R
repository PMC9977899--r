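test_that("a model without free directed parameters fits in closed form", {
  fx <- fig5_model()
  fit <- fit_snlls(fx$model, S = matrix(c(2, 1, 1, 2), 2), N = 100,
                   weight = "uls")
  expect_equal(fit$iterations, 0L)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta_omega), c(1, 1, 1))
  expect_lt(abs(fit$objective), 1e-12)
  expect_equal(det(implied_sigma(fx$model, fit$theta)), 3)
})

test_that("zero-residual recovery: population moments give back population values", {
  fx <- fig2_model()
  S_pop <- implied_sigma(fx$model, fx$theta0)
  for (fitter in list(fit_snlls, fit_full_ls)) {
    fit <- fitter(fx$model, S = S_pop, N = 1000, weight = "gls")
    expect_true(fit$converged)
    expect_lt(fit$objective, 1e-10)
    expect_equal(unname(fit$theta[names(fx$theta0)]), unname(fx$theta0),
                 tolerance = 1e-6)
  }
})

test_that("SNLLS and full LS reach the same minimum of the same objective", {
  set.seed(701)
  fx <- fig2_model()
  S <- implied_sigma(fx$model, fx$theta0)
  S <- S + 0.08 * rand_pd(6, jitter = 0.1)   # perturb off the model surface
  for (w in c("uls", "gls")) {
    a <- fit_snlls(fx$model, S = S, N = 500, weight = w)
    b <- fit_full_ls(fx$model, S = S, N = 500, weight = w)
    expect_true(a$converged && b$converged)
    expect_equal(unname(a$theta), unname(b$theta), tolerance = 1e-4)
    expect_equal(a$objective, b$objective, tolerance = 1e-8)
    expect_gte(b$objective, 0)
  }
})

test_that("the back-substituted linear parameters reproduce solve_linear exactly", {
  set.seed(707)
  fx <- fig2_model()
  S <- implied_sigma(fx$model, fx$theta0) + 0.05 * rand_pd(6, jitter = 0.1)
  W <- weight_matrix("gls", S = S)
  fit <- fit_snlls(fx$model, S = S, N = 500, weight = W)
  w <- solve_linear(build_G(fx$model, unname(fit$theta_lambda)), W, vech(S))
  expect_identical(unname(fit$theta_omega), w)
})

test_that("starting values default to 0.5 per directed parameter, overridable", {
  fx <- fig2_model()
  st <- starting_values(fx$model)
  expect_equal(unname(st), rep(0.5, 5))
  expect_identical(names(st), fx$model$par_lambda)
  st2 <- starting_values(fx$model, override = c(beta = 0.25))
  expect_equal(unname(st2[c("lambda2", "beta")]), c(0.5, 0.25))
  expect_length(starting_values(fig5_model()$model), 0)
  expect_error(starting_values(fx$model, override = c(nope = 1)),
               class = "snllsem_label_error")
})

test_that("mean parameters are recovered by the same single linear solve", {
  m <- parse_model("
    latent: f
    f -> y1 = 1
    f -> y2 lam2
    f -> y3 lam3
    y1 <-> y1 e1
    y2 <-> y2 e2
    y3 <-> y3 e3
    f <-> f vf
    mean: f mf
    mean: y2 m2")
  theta0 <- c(lam2 = 0.7, lam3 = 0.5, e1 = 0.5, e2 = 0.6, e3 = 0.8,
              vf = 1, mf = 2, m2 = -1)
  S_pop <- implied_sigma(m, unname(theta0[theta_names(m)]))
  mu_pop <- implied_mu(m, unname(theta0[theta_names(m)]))
  fit <- fit_snlls(m, S = S_pop, N = 100, means = mu_pop, weight = "gls")
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[names(theta0)]), unname(theta0),
               tolerance = 1e-6)
  expect_error(fit_snlls(m, S = S_pop, N = 100, weight = "gls"),
               class = "snllsem_data_error")
})

test_that("negative variance estimates are reported with a warning, not an error", {
  m <- parse_model("a <-> a va\nb <-> b vb\na <-> b cab")
  S <- matrix(c(-0.5, 0.2, 0.2, 1), 2)  # not a covariance matrix on purpose
  expect_warning(fit <- fit_snlls(m, S = S, N = 50, weight = "uls"),
                 "negative variance")
  expect_equal(unname(fit$theta_omega["va"]), -0.5)
})

test_that("estimates agree between raw-data and moment-matrix input", {
  set.seed(711)
  fx <- fig2_model()
  dat <- simulate_data(fx$model, fx$theta0, 400, seed = 99)
  sm <- sample_moments(dat)
  f1 <- fit_snlls(fx$model, data = dat, weight = "gls")
  f2 <- fit_snlls(fx$model, S = sm$S, N = sm$N, weight = "gls")
  expect_equal(f1$theta, f2$theta)
})

test_that("IRLS reweighting reaches the ML fixed point", {
  # saturated model: implied covariance must reproduce S exactly
  fx <- fig5_model()
  S <- matrix(c(2.3, 0.9, 0.9, 1.7), 2)
  fit <- irls_ml(fx$model, S = S, N = 200)
  expect_true(fit$converged)
  expect_equal(implied_sigma(fx$model, fit$theta), S, ignore_attr = TRUE,
               tolerance = 1e-8)

  # degenerate outer tolerance: one sweep, identical to SNLLS-GLS
  f2 <- fig2_model()
  S2 <- implied_sigma(f2$model, f2$theta0) + 0.05 * rand_pd(6, jitter = 0.1)
  one <- irls_ml(f2$model, S = S2, N = 300, control = list(outer_tol = Inf))
  gls <- fit_snlls(f2$model, S = S2, N = 300, weight = "gls")
  expect_equal(one$outer_iterations, 1L)
  expect_equal(unname(one$theta), unname(gls$theta))

  # overidentified model: estimates within sampling error of GLS
  set.seed(721)
  dat <- simulate_data(f2$model, f2$theta0, 5000, seed = 7)
  sm <- sample_moments(dat)
  ml <- irls_ml(f2$model, S = sm$S, N = sm$N)
  gl <- fit_snlls(f2$model, S = sm$S, N = sm$N, weight = "gls")
  expect_true(ml$converged)
  expect_equal(unname(ml$theta), unname(gl$theta), tolerance = 0.1)
})

test_that("non-convergence is recorded, not raised", {
  fx <- fig2_model()
  set.seed(731)
  dat <- simulate_data(fx$model, fx$theta0, 12, seed = 3)
  S <- sample_moments(dat)$S
  fit <- suppressWarnings(
    fit_full_ls(fx$model, S = S, N = 12, weight = "gls",
                control = list(iter_max = 2)))
  expect_s3_class(fit, "sem_fit")
  expect_false(fit$converged)
})
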