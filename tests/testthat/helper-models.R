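# fixtures built in code: random acyclic models, bindings, and small
# numeric oracles shared across the test files

fig5_text <- "
  latent: l
  l -> x1 = 1
  l -> x2 = 1
  x1 <-> x1 omega1
  x2 <-> x2 omega2
  l  <-> l  omega_l"

# random acyclic RAM model: every node gets a free variance; directed
# edges respect a random topological order; optional equality ties and
# fixed nonzero constants in Lambda/Omega
random_ram_model <- function(m_obs = sample(2:4, 1), m_lat = sample(0:2, 1),
                             p_edge = 0.4, p_cov = 0.2,
                             ties = FALSE, constants = FALSE) {
  obs <- paste0("o", seq_len(m_obs))
  lat <- if (m_lat) paste0("f", seq_len(m_lat)) else character()
  nodes <- c(obs, lat)
  ord <- sample(nodes)
  lines <- character()
  if (m_lat) lines <- c(lines, paste("latent:", paste(lat, collapse = " ")))
  eid <- 0
  for (a in seq_along(ord)) for (b in seq_along(ord)) {
    if (a >= b || stats::runif(1) > p_edge) next
    eid <- eid + 1
    tail <- if (constants && stats::runif(1) < 0.25)
      sprintf("= %.3f", stats::runif(1, 0.2, 0.9)) else sprintf("b%d", eid)
    lines <- c(lines, sprintf("%s -> %s %s", ord[a], ord[b], tail))
  }
  vid <- 0
  for (n in nodes) {
    vid <- vid + 1
    tail <- if (constants && stats::runif(1) < 0.2)
      sprintf("= %.3f", stats::runif(1, 0.5, 1.5)) else sprintf("v%d", vid)
    lines <- c(lines, sprintf("%s <-> %s %s", n, n, tail))
  }
  cid <- 0
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
    if (a >= b || stats::runif(1) > p_cov) next
    cid <- cid + 1
    lines <- c(lines, sprintf("%s <-> %s c%d", nodes[a], nodes[b], cid))
  }
  m <- parse_model(paste(lines, collapse = "\n"))
  if (ties && length(m$par_lambda) >= 2) {
    # re-parse with the first two free directed labels tied
    lines <- sub(paste0("\\b", m$par_lambda[2], "\\b"), m$par_lambda[1], lines)
    m <- parse_model(paste(lines, collapse = "\n"))
  }
  m
}

# parameter draw: positive variances, small covariances, modest loadings
random_bindings <- function(model) {
  th <- numeric(0)
  for (lb in model$par_lambda) th[lb] <- stats::runif(1, -0.8, 0.8)
  for (lb in model$par_omega) {
    pos <- index_maps(model)$C[[lb]][1, ]
    th[lb] <- if (pos[1] == pos[2]) stats::runif(1, 0.5, 1.5)
              else stats::runif(1, -0.2, 0.2)
  }
  for (lb in model$par_gamma) th[lb] <- stats::runif(1, -1, 1)
  th[theta_names(model)]
}

# random confirmatory-factor-type model (well identified) with its
# population values, for estimator-equivalence checks
random_cfa_model <- function() {
  k <- sample(1:2, 1)
  # a single factor needs >= 3 indicators to be identified; with two
  # correlated factors, two indicators each suffice
  nind <- if (k == 1) sample(3:4, 1) else sample(2:3, k, replace = TRUE)
  lines <- c(paste("latent:", paste(paste0("f", seq_len(k)), collapse = " ")))
  pop <- c()
  v <- 0
  for (f in seq_len(k)) for (i in seq_len(nind[f])) {
    v <- v + 1
    if (i == 1) {
      lines <- c(lines, sprintf("f%d -> y%d = 1", f, v))
    } else {
      lab <- sprintf("L%d", v)
      lines <- c(lines, sprintf("f%d -> y%d %s", f, v, lab))
      pop[lab] <- stats::runif(1, 0.6, 1.2)
    }
  }
  for (i in seq_len(v)) {
    lab <- sprintf("e%d", i)
    lines <- c(lines, sprintf("y%d <-> y%d %s", i, i, lab))
    pop[lab] <- stats::runif(1, 0.6, 1.4)
  }
  for (f in seq_len(k)) {
    lab <- sprintf("psi%d", f)
    lines <- c(lines, sprintf("f%d <-> f%d %s", f, f, lab))
    pop[lab] <- stats::runif(1, 0.7, 1.3)
  }
  if (k == 2) {
    lines <- c(lines, "f1 <-> f2 psi12")
    pop["psi12"] <- stats::runif(1, 0.1, 0.3)
  }
  model <- parse_model(paste(lines, collapse = "\n"))
  list(model = model, theta0 = pop[theta_names(model)])
}

# split a full theta vector into its three blocks by position
split_theta_for_test <- function(model, theta) {
  nl <- length(model$par_lambda); no <- length(model$par_omega)
  ng <- length(model$par_gamma)
  list(lambda = unname(theta[seq_len(nl)]),
       omega = unname(theta[nl + seq_len(no)]),
       gamma = unname(theta[nl + no + seq_len(ng)]))
}

# central finite differences, the independent oracle for every analytic
# derivative in the package
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(n) {
    xp <- x; xp[n] <- xp[n] + h
    xm <- x; xm[n] <- xm[n] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

rand_pd <- function(m, jitter = 0.5) {
  A <- matrix(stats::rnorm(m * m), m)
  crossprod(A) / m + jitter * diag(m)
}
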