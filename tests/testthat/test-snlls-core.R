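# the variable-projection machinery: G assembly, linear solve, reduced
# objective and the analytic Jacobian, each against an independent
# numeric oracle

test_that("G for the two-indicator model matches the hand evaluation", {
  m <- fig5_model()$model
  G <- build_G(m)
  expect_equal(G$G_sigma,
               rbind(c(1, 0, 1), c(0, 0, 1), c(0, 1, 1)),
               ignore_attr = TRUE)
  expect_equal(G$offset_sigma, c(0, 0, 0))
  expect_true(all(G$pattern == (G$G_sigma != 0)))
})

test_that("with Lambda = 0 and diagonal Omega, G is a 0/1 selection matrix", {
  m <- parse_model("a <-> a va\nb <-> b vb\nc <-> c vc")
  G <- build_G(m)$G_sigma
  expect_true(all(G %in% c(0, 1)))
  expect_equal(colSums(G), c(1, 1, 1), ignore_attr = TRUE)
  im <- index_maps(m)
  for (s in 1:3) {
    r <- which(G[, s] == 1)
    expect_equal(unname(im$D[r, ]), unname(im$C[[s]][1, ]))
  }
})

test_that("linearity identity: G theta + offset reproduces vech(Sigma) and mu", {
  set.seed(601)
  for (rep in 1:30) {
    m <- random_ram_model(ties = rep %% 2 == 0, constants = rep %% 3 == 0)
    th <- random_bindings(m)
    sp <- split_theta_for_test(m, th)
    G <- build_G(m, sp$lambda)
    expect_lt(max(abs(G$G_sigma %*% sp$omega + G$offset_sigma -
                        vech(implied_sigma(m, th)))), 1e-10)
  }

  # mean block, with a fixed nonzero constant routed into the offset
  m <- parse_model(paste(fig5_text, "\nmean: l g\nmean: x1 = 0.3"))
  th <- c(1.2, 0.7, 0.9, 1.5)
  G <- build_G(m)
  expect_equal(drop(G$G_mu %*% 1.5 + G$offset_mu),
               implied_mu(m, th), ignore_attr = TRUE)
  expect_equal(G$offset_mu, c(0.3, 0))
})

test_that("equality ties sum columns and fixed constants move to the offset", {
  base <- "latent: f\nf -> a = 1\nf -> b lam\nf <-> f vf\n"
  tied <- parse_model(paste0(base, "a <-> a ve\nb <-> b ve"))
  free <- parse_model(paste0(base, "a <-> a v1\nb <-> b v2"))
  lam <- 0.8
  Gt <- build_G(tied, lam)
  Gf <- build_G(free, lam)
  expect_equal(ncol(Gt$G_sigma), 2)
  # the tied column is the sum of the two untied ones
  expect_equal(Gt$G_sigma[, 2], Gf$G_sigma[, 2] + Gf$G_sigma[, 3])

  fixed <- parse_model(paste0(base, "a <-> a = 0.4\nb <-> b ve"))
  Gx <- build_G(fixed, lam)
  expect_equal(Gx$offset_sigma, 0.4 * Gf$G_sigma[, 2])
  th_fixed <- c(lam, 0.9, 1.1)  # (lam, ve, vf)
  expect_equal(drop(Gx$G_sigma %*% c(0.9, 1.1) + Gx$offset_sigma),
               vech(implied_sigma(fixed, th_fixed)))
})

test_that("solve_linear equals a generic weighted LS solver and handles rank deficiency", {
  m <- fig5_model()$model
  th <- solve_linear(build_G(m), weight_matrix("uls", m_obs = 2), c(2, 1, 2))
  expect_equal(th, c(1, 1, 1), ignore_attr = TRUE)

  set.seed(611)
  for (rep in 1:10) {
    G <- matrix(rnorm(21 * 5), 21, 5)
    V <- rand_pd(21)
    s <- rnorm(21)
    got <- solve_linear(G, V, s)
    want <- solve(t(G) %*% V %*% G, t(G) %*% V %*% s)
    expect_equal(got, drop(want), tolerance = 1e-10)
  }

  # duplicated column: minimal-norm solution splits the weight equally,
  # objective unchanged
  G1 <- matrix(rnorm(12), 6, 2)
  Gdup <- cbind(G1, G1[, 2])
  V <- diag(6); s <- rnorm(6)
  w1 <- solve_linear(G1, V, s)
  wd <- solve_linear(Gdup, V, s)
  expect_equal(wd[2], wd[3])
  expect_equal(wd[2] + wd[3], w1[2])
  expect_equal(reduced_objective(Gdup, V, s), reduced_objective(G1, V, s))
  expect_error(solve_linear(G1, V, c(s[-6], NaN)), class = "snllsem_nonfinite")
})

test_that("reduced objective is the profiled discrepancy, zero on exact fit", {
  m <- fig5_model()$model
  V <- weight_matrix("uls", m_obs = 2)
  set.seed(621)
  for (rep in 1:5) {
    s <- rnorm(3)
    expect_lt(abs(reduced_objective(build_G(m), V, s)), 1e-12)  # saturated
  }
  for (rep in 1:10) {
    G <- matrix(rnorm(10 * 3), 10, 3)
    V <- rand_pd(10); s <- rnorm(10)
    f <- reduced_objective(G, V, s)
    w <- solve_linear(G, V, s)
    r <- s - drop(G %*% w)
    expect_equal(f, drop(t(r) %*% V %*% r), tolerance = 1e-10)
    expect_gte(f, -1e-12)
    expect_lt(abs(reduced_objective(G, V, drop(G %*% rnorm(3)))), 1e-12)
  }
})

test_that("variable projection minimizes the conditional problem", {
  set.seed(631)
  f2 <- fig2_model()
  sp <- split_theta_for_test(f2$model, f2$theta0)
  G <- build_G(f2$model, sp$lambda)
  V <- rand_pd(21)
  s <- vech(implied_sigma(f2$model, f2$theta0)) + rnorm(21, sd = 0.2)
  f_at <- function(w) { r <- s - drop(G$G %*% w); drop(t(r) %*% V %*% r) }
  fstar <- reduced_objective(G, V, s)
  for (rep in 1:100)
    expect_gte(f_at(solve_linear(G, V, s) + rnorm(8, sd = 0.5)), fstar - 1e-10)
})

test_that("dB spot check: two-node chain has dB[2,1]/dLambda[2,1] = 1", {
  m <- parse_model("a -> b lam\na <-> a va\nb <-> b vb")
  for (lam in c(0, 0.4, -0.7)) {
    dG <- build_dG(m, lam)
    B <- solve(diag(2) - materialize(m, c(lam, 1, 1))$Lambda)
    expect_equal(B[2, 2] * B[1, 1], 1)   # B = I + Lambda here
    h <- 1e-6
    Bp <- solve(diag(2) - materialize(m, c(lam + h, 1, 1))$Lambda)
    Bm <- solve(diag(2) - materialize(m, c(lam - h, 1, 1))$Lambda)
    expect_equal((Bp[2, 1] - Bm[2, 1]) / (2 * h), 1, tolerance = 1e-6)
  }
})

test_that("DG has the documented vec-order shape and zero columns when dim(theta_Lambda)=0", {
  m5 <- fig5_model()$model
  dG5 <- build_dG(m5)
  expect_equal(dim(dG5$DG), c(3L * 3L, 0L))

  m <- parse_model("latent: f\nf -> a lam\nf -> b = 1\na <-> a va\nb <-> b vb\nf <-> f vf")
  dG <- build_dG(m, 0.4)
  G <- build_G(m, 0.4)
  expect_equal(dim(dG$DG), c(nrow(G$G) * ncol(G$G), 1L))
  # vec order: entry t of vec(G) is G[t - k*floor((t-1)/k), ceiling(t/k)]
  k <- nrow(G$G)
  for (t in seq_len(length(G$G))) {
    r <- t - k * floor((t - 1) / k); cc <- ceiling(t / k)
    expect_identical(as.vector(G$G)[t], G$G[r, cc])
  }
})

test_that("DG matches central finite differences of G", {
  # fixed two-indicator chain
  m <- parse_model("latent: f\nf -> a lam\nf -> b = 1\na <-> a va\nb <-> b vb\nf <-> f vf")
  lam <- 0.4
  dG <- build_dG(m, lam)
  fd <- (build_G(m, lam + 1e-6)$G - build_G(m, lam - 1e-6)$G) / 2e-6
  expect_equal(dG$dG_list[[1]], fd, tolerance = 1e-6)

  set.seed(641)
  for (rep in 1:12) {
    m <- random_ram_model(m_obs = sample(2:5, 1), m_lat = sample(0:3, 1),
                          ties = rep %% 3 == 0, constants = rep %% 2 == 0)
    if (!length(m$par_lambda)) next
    tl <- runif(length(m$par_lambda), -0.6, 0.6)
    dG <- build_dG(m, tl)
    for (n in seq_along(tl)) {
      tp <- tl; tp[n] <- tp[n] + 1e-6
      tm <- tl; tm[n] <- tm[n] - 1e-6
      Gp <- build_G(m, tp); Gm <- build_G(m, tm)
      fd <- (Gp$G - Gm$G) / 2e-6
      expect_equal(dG$dG_list[[n]], fd, tolerance = 1e-5)
      fdo <- (Gp$offset - Gm$offset) / 2e-6
      expect_equal(dG$d_offset[, n], fdo, tolerance = 1e-5)
    }
  }
})

test_that("the reduced gradient matches finite differences and vanishes at exact fit", {
  f2 <- fig2_model()
  m <- f2$model
  sp <- split_theta_for_test(m, f2$theta0)
  s_pop <- vech(implied_sigma(m, f2$theta0))
  V <- weight_matrix("gls", S = implied_sigma(m, f2$theta0))
  g0 <- reduced_gradient(m, sp$lambda, V, s_pop)
  expect_lt(max(abs(g0)), 1e-8)

  m5 <- fig5_model()$model
  expect_length(reduced_gradient(m5, numeric(0), diag(3), c(2, 1, 2)), 0)

  set.seed(651)
  for (rep in 1:10) {
    mm <- random_ram_model(ties = rep %% 3 == 0, constants = rep %% 2 == 0)
    if (!length(mm$par_lambda)) next
    tl <- runif(length(mm$par_lambda), -0.5, 0.5)
    nD <- index_maps(mm)$n_sigma
    V <- rand_pd(nD)
    s <- vech(implied_sigma(mm, random_bindings(mm))) + rnorm(nD, sd = 0.3)
    got <- reduced_gradient(mm, tl, V, s)
    want <- fd_gradient(function(x) reduced_objective(build_G(mm, x), V, s), tl)
    expect_equal(got, want, tolerance = 1e-5 * max(1, max(abs(want))))
  }
})

test_that("G and DG entries vary continuously with the directed parameters", {
  m <- fig2_model()$model
  tl <- c(0.8, 0.6, 0.8, 0.6, 0.25)
  eps <- 1e-7
  tl2 <- tl + eps
  dG1 <- build_dG(m, tl); dG2 <- build_dG(m, tl2)
  expect_lt(max(abs(build_G(m, tl)$G - build_G(m, tl2)$G)), 1e-5)
  expect_lt(max(abs(dG1$DG - dG2$DG)), 1e-5)
})
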