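# the trek engine is the package's independent symbolic oracle; these
# tests pin the worked bi-factor examples and the oracle's equivalence
# with the matrix pipeline

fig1_graph <- function() mixed_graph(fig1_model()$model)

test_that("bi-factor worked example: cov(X2, X6) has exactly two treks", {
  g <- fig1_graph()
  treks <- enumerate_treks(g, "X2", "X6")
  expect_length(treks, 2)
  poly <- implied_cov_trek(g, "X2", "X6")
  expect_identical(format(poly),
                   "beta2*beta6*omega_G + lambda2*lambda6*omega_l")
  val <- implied_cov_trek(g, "X2", "X6",
                          bindings = c(lambda2 = 0.8, omega_l = 0.3,
                                       lambda6 = 0.5, beta2 = 0.4,
                                       omega_G = 1, beta6 = 0.6))
  expect_equal(val, 0.8 * 0.3 * 0.5 + 0.4 * 1 * 0.6)  # 0.36
})

test_that("bi-factor worked example: var(X3) has three treks incl. the single node", {
  g <- fig1_graph()
  treks <- enumerate_treks(g, "X3", "X3")
  expect_length(treks, 3)
  kinds <- vapply(treks, `[[`, character(1), "kind")
  tops <- vapply(treks, function(t) t$anchor[1], character(1))
  expect_setequal(tops[kinds == "top"], c("zeta1", "G", "X3"))
  poly <- implied_cov_trek(g, "X3", "X3")
  expect_identical(format(poly),
                   "omega_3 + beta3*beta3*omega_G + lambda3*lambda3*omega_zeta1")
  val <- implied_cov_trek(g, "X3", "X3",
                          bindings = c(lambda3 = 0.5, omega_zeta1 = 1,
                                       beta3 = 0.4, omega_G = 1, omega_3 = 0.3))
  expect_equal(val, 0.5^2 + 0.4^2 + 0.3)  # 0.71
})

test_that("trek monomials carry exactly one undirected factor", {
  g <- fig1_graph()
  for (pair in list(c("X1", "X4"), c("X2", "X2"), c("X3", "X5"))) {
    for (tr in enumerate_treks(g, pair[1], pair[2])) {
      mn <- trek_monomial(tr, g)
      expect_false(is.na(mn$omega))   # every Omega entry here is a free label
      expect_false(any(mn$lambda %in% c(g$variances$label, g$covariances$label)))
    }
  }
})

test_that("an isolated node has the single-node trek only", {
  m <- parse_model("a <-> a va")
  g <- mixed_graph(m)
  treks <- enumerate_treks(g, "a", "a")
  expect_length(treks, 1)
  expect_identical(format(implied_cov_trek(g, "a", "a")), "va")
})

test_that("path sums reproduce the inverse of I - Lambda", {
  chain <- parse_model("a -> b p\nb -> c q\na <-> a va\nb <-> b vb\nc <-> c vc")
  g <- mixed_graph(chain)
  expect_identical(format(path_sum_inverse(g, "a", "c")), "p*q")
  expect_identical(format(path_sum_inverse(g, "b", "b")), "1")
  expect_equal(path_sum_inverse(g, "a", "c", bindings = c(p = 0.3, q = 0.5)), 0.15)

  f5 <- mixed_graph(fig5_model()$model)
  expect_identical(format(path_sum_inverse(f5, "l", "x1")), "1")

  set.seed(77)
  for (rep in 1:10) {
    m <- random_ram_model()
    th <- random_bindings(m)
    B <- solve(diag(length(m$nodes)) - materialize(m, th)$Lambda)
    g <- mixed_graph(m)
    for (i in seq_along(m$nodes)) for (j in seq_along(m$nodes)) {
      expect_equal(path_sum_inverse(g, m$nodes[j], m$nodes[i], bindings = th),
                   B[i, j], tolerance = 1e-10)
    }
  }
})

test_that("trek enumeration refuses directed cycles", {
  cyc <- parse_model("x1 -> x2 a\nx2 -> x1 b\nx1 <-> x1 v1\nx2 <-> x2 v2")
  expect_error(enumerate_treks(mixed_graph(cyc), "x1", "x2"),
               class = "snllsem_cyclic")
  expect_error(path_sum_inverse(mixed_graph(cyc), "x1", "x2"),
               class = "snllsem_cyclic")
})

test_that("trek counts are symmetric and ordering is deterministic", {
  g <- fig1_graph()
  for (pair in list(c("X2", "X6"), c("X1", "X3"), c("X5", "X5"))) {
    t_ij <- enumerate_treks(g, pair[1], pair[2])
    t_ji <- enumerate_treks(g, pair[2], pair[1])
    expect_length(t_ji, length(t_ij))
  }
  a <- enumerate_treks(g, "X2", "X6")
  b <- enumerate_treks(g, "X2", "X6")
  expect_identical(a, b)
})

test_that("oracle equivalence: trek polynomial matches the matrix formula", {
  set.seed(505)
  for (rep in 1:25) {
    m <- random_ram_model(constants = rep %% 4 == 0)
    th <- random_bindings(m)
    Sig <- implied_sigma(m, th)
    g <- mixed_graph(m)
    obs <- m$nodes[seq_len(m$m_obs)]
    for (i in seq_along(obs)) for (j in seq_len(i)) {
      expect_equal(implied_cov_trek(g, obs[i], obs[j], bindings = th),
                   Sig[i, j], tolerance = 1e-10)
    }
  }
})
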