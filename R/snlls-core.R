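# Variable-projection core.
#
# With B = (I - Lambda)^-1, each half-vectorized implied covariance entry
# is linear in the undirected parameters:
#
#   sigma_r = sum_{(l,k) in C_s} [ B[i,l] B[j,k] +
#                                  (k != l) B[i,k] B[j,l] ] * (theta_Omega)_s
#
# with (i,j) = D_r, stacked over the vech positions D and parameter
# positions C into sigma = G_sigma(theta_Lambda) theta_Omega + offset.
# The mean block is mu = G_mu theta_gamma + offset with G_mu[i, s] =
# sum_{a in A_s} B[i, a].  Equality-constrained labels sum the columns of
# all tied positions; fixed nonzero Omega/gamma constants accumulate
# their contributions into the offset vector instead of G, so the
# linearity identity G theta + offset = (vech Sigma, mu) holds for every
# parameter value.
#
# The Jacobian DG follows from d B[k,l] / d Lambda[i,j] = B[k,i] B[j,l]
# by the product rule, summed over tied Lambda positions.

# precomputed per-model structure reused by every evaluation in a fit
model_context <- function(model) {
  im <- index_maps(model)
  om <- model$omega
  fo <- om[is.na(om$label) & om$value != 0, , drop = FALSE]
  ga <- model$gamma
  fg <- ga[is.na(ga$label) & ga$value != 0, , drop = FALSE]
  list(model = model, im = im,
       m = length(model$nodes), m_obs = model$m_obs,
       n_lam = length(model$par_lambda),
       n_om = length(model$par_omega),
       n_gam = length(model$par_gamma),
       fixed_omega = fo, fixed_gamma = fg,
       has_mean = nrow(model$gamma) > 0L)
}

# one sigma-block column (or its theta_Lambda-derivative when dB given)
# for Omega positions P, vectorized over the vech rows
g_sigma_col <- function(B, Dm, P, dB = NULL) {
  i <- Dm[, 1]; j <- Dm[, 2]
  out <- numeric(nrow(Dm))
  for (t in seq_len(nrow(P))) {
    l <- P[t, 1]; k <- P[t, 2]
    if (is.null(dB)) {
      term <- B[i, l] * B[j, k]
      if (l != k) term <- term + B[i, k] * B[j, l]
    } else {
      term <- dB[i, l] * B[j, k] + B[i, l] * dB[j, k]
      if (l != k) term <- term + dB[i, k] * B[j, l] + B[i, k] * dB[j, l]
    }
    out <- out + term
  }
  out
}

# numeric assembly given B; returns sigma/mu blocks and offsets
build_G_ctx <- function(ctx, B) {
  im <- ctx$im; Dm <- im$D
  Gs <- matrix(0, nrow(Dm), ctx$n_om)
  for (s in seq_len(ctx$n_om)) Gs[, s] <- g_sigma_col(B, Dm, im$C[[s]])
  off_s <- numeric(nrow(Dm))
  if (nrow(ctx$fixed_omega))
    for (t in seq_len(nrow(ctx$fixed_omega)))
      off_s <- off_s + ctx$fixed_omega$value[t] *
        g_sigma_col(B, Dm, cbind(ctx$fixed_omega$i[t], ctx$fixed_omega$j[t]))
  Gm <- matrix(0, ctx$m_obs, ctx$n_gam)
  for (s in seq_len(ctx$n_gam)) {
    a <- im$A[[s]]
    Gm[, s] <- rowSums(B[seq_len(ctx$m_obs), a, drop = FALSE])
  }
  off_m <- numeric(ctx$m_obs)
  if (nrow(ctx$fixed_gamma))
    off_m <- unname(drop(B[seq_len(ctx$m_obs), ctx$fixed_gamma$i, drop = FALSE] %*%
                           ctx$fixed_gamma$value))
  list(G_sigma = unname(Gs), G_mu = unname(Gm),
       offset_sigma = unname(off_s), offset_mu = off_m)
}

stack_G <- function(ctx, parts) {
  if (ctx$has_mean) {
    G <- block_diag(parts$G_sigma, parts$G_mu)
    offset <- c(parts$offset_sigma, parts$offset_mu)
  } else {
    G <- parts$G_sigma
    offset <- parts$offset_sigma
  }
  list(G = G, offset = offset)
}

# structural sparsity: reachability of the directed part marks which
# B entries can ever be nonzero, hence which G entries can
reachability <- function(model) {
  m <- length(model$nodes)
  R <- diag(m) > 0
  lam <- model$lambda
  if (nrow(lam)) {
    A <- matrix(FALSE, m, m)
    A[cbind(lam$i, lam$j)] <- TRUE    # edge j -> i
    for (step in seq_len(m)) {
      Rn <- R | ((R %*% A) > 0)
      if (identical(Rn, R)) break
      R <- Rn
    }
  }
  R
}

g_pattern <- function(ctx) {
  R <- reachability(ctx$model)
  Dm <- ctx$im$D
  pat <- matrix(FALSE, nrow(Dm), ctx$n_om)
  for (s in seq_len(ctx$n_om)) {
    P <- ctx$im$C[[s]]
    for (t in seq_len(nrow(P))) {
      l <- P[t, 1]; k <- P[t, 2]
      pat[, s] <- pat[, s] | (R[Dm[, 1], l] & R[Dm[, 2], k]) |
        (l != k & R[Dm[, 1], k] & R[Dm[, 2], l])
    }
  }
  pat
}

#' Assemble the design matrix G of the linear (undirected and mean) parameters
#'
#' At a fixed value of the directed parameters, the model-implied moment
#' vector is an affine function of the undirected and mean parameters:
#' \code{vech(Sigma) = G_sigma theta_Omega + offset_sigma} and \code{mu =
#' G_mu theta_gamma + offset_mu}.  \code{build_G()} computes \code{B =
#' (I - Lambda)^-1} once and fills the entries by looping over the
#' position tuples C (Omega parameters) x D (vech slots) and A (mean
#' parameters).  Columns of equality-constrained labels are summed over
#' all tied positions; fixed nonzero Omega/gamma constants contribute to
#' the offset vector instead of G.
#'
#' @param model a \code{ram_model}.
#' @param theta_lambda numeric vector of the directed parameters (length
#'   \code{length(model$par_lambda)}).
#' @return an object of class \code{snlls_G}: \code{G_sigma}
#'   (\code{|D| x dim(theta_Omega)}), \code{G_mu}, the block-diagonal
#'   stacked \code{G} (equal to \code{G_sigma} for models without a mean
#'   structure), the offset vectors, and the structural sparsity
#'   \code{pattern} of \code{G_sigma}.
#' @export
build_G <- function(model, theta_lambda = numeric(0)) {
  ctx <- model_context(model)
  if (length(theta_lambda) != ctx$n_lam)
    stop_snllsem("theta_lambda has the wrong length", "snllsem_dim_error")
  B <- safe_binv(fill_lambda(model, theta_lambda))
  parts <- build_G_ctx(ctx, B)
  st <- stack_G(ctx, parts)
  structure(c(parts, st, list(pattern = g_pattern(ctx),
                              has_mean = ctx$has_mean)),
            class = "snlls_G")
}

as_G <- function(G) {
  if (inherits(G, "snlls_G")) return(G)
  if (is.list(G) && !is.null(G$G) && !is.null(G$offset)) return(G)
  list(G = as.matrix(G), offset = numeric(nrow(as.matrix(G))))
}

#' Closed-form solve for the linear parameters
#'
#' Given the design matrix at the current directed parameters, the
#' conditional least squares minimizer of the undirected (and mean)
#' parameters is \code{(G^T V G)^+ G^T V (s - offset)}.  When \code{G^T V G}
#' is invertible this equals the usual weighted normal-equations solution;
#' otherwise the Moore-Penrose pseudoinverse (singular values below
#' \code{1e-10} times the largest treated as zero) returns the
#' minimum-norm minimizer, so rank deficiency is handled rather than
#' raised.
#'
#' @param G an \code{snlls_G} (or a plain design matrix, taken with zero
#'   offset).
#' @param V an \code{snlls_weight} or a weight matrix.
#' @param s observed moment vector (\code{vech(S)}, with the sample
#'   means appended for models with a mean structure).
#' @return numeric vector of linear-parameter estimates (undirected
#'   parameters first, then means).
#' @export
solve_linear <- function(G, V, s) {
  G <- as_G(G); Vm <- weight_V(V)
  if (any(!is.finite(s)))
    stop_snllsem("non-finite values in the observed moment vector", "snllsem_nonfinite")
  sh <- s - G$offset
  VG <- Vm %*% G$G
  pinv_solve(crossprod(G$G, VG), drop(crossprod(VG, sh)))
}

#' Reduced (variable-projection) objective
#'
#' The least squares discrepancy profiled over the linear parameters:
#' \code{F(theta_Lambda) = min_w (s - offset - G w)^T V (s - offset -
#' G w)}, evaluated by substituting the \code{\link{solve_linear}}
#' minimizer.  Nonnegative up to rounding of order \code{1e-12}.
#'
#' @inheritParams solve_linear
#' @return a scalar.
#' @export
reduced_objective <- function(G, V, s) {
  G <- as_G(G); Vm <- weight_V(V)
  w <- solve_linear(G, Vm, s)
  r <- (s - G$offset) - drop(G$G %*% w)
  drop(crossprod(r, Vm %*% r))
}

# per-parameter dB matrices: dB/d(theta_Lambda)_n summed over tied
# Lambda positions, using dB/dLambda[u,v] = B[,u] outer B[v,]
dB_list <- function(ctx, B) {
  lapply(seq_len(ctx$n_lam), function(n) {
    Q <- ctx$im$E[[n]]
    dB <- matrix(0, ctx$m, ctx$m)
    for (t in seq_len(nrow(Q)))
      dB <- dB + B[, Q[t, 1]] %o% B[Q[t, 2], ]
    dB
  })
}

# derivative of the stacked (G, offset) w.r.t. (theta_Lambda)_n
dG_ctx_n <- function(ctx, B, dB) {
  im <- ctx$im; Dm <- im$D
  dGs <- matrix(0, nrow(Dm), ctx$n_om)
  for (s in seq_len(ctx$n_om))
    dGs[, s] <- g_sigma_col(B, Dm, im$C[[s]], dB)
  doff_s <- numeric(nrow(Dm))
  if (nrow(ctx$fixed_omega))
    for (t in seq_len(nrow(ctx$fixed_omega)))
      doff_s <- doff_s + ctx$fixed_omega$value[t] *
        g_sigma_col(B, Dm, cbind(ctx$fixed_omega$i[t], ctx$fixed_omega$j[t]), dB)
  dGm <- matrix(0, ctx$m_obs, ctx$n_gam)
  for (s in seq_len(ctx$n_gam))
    dGm[, s] <- rowSums(dB[seq_len(ctx$m_obs), im$A[[s]], drop = FALSE])
  doff_m <- numeric(ctx$m_obs)
  if (nrow(ctx$fixed_gamma))
    doff_m <- unname(drop(dB[seq_len(ctx$m_obs), ctx$fixed_gamma$i, drop = FALSE] %*%
                            ctx$fixed_gamma$value))
  if (ctx$has_mean)
    list(dG = block_diag(unname(dGs), unname(dGm)),
         doffset = c(unname(doff_s), doff_m))
  else
    list(dG = unname(dGs), doffset = unname(doff_s))
}

#' Analytic Jacobian of G with respect to the directed parameters
#'
#' Differentiates every entry of the stacked design matrix through
#' \code{B = (I - Lambda)^-1}, using \code{dB[k,l]/dLambda[i,j] = B[k,i]
#' B[j,l]} and the product rule, with contributions summed over all tied
#' positions of an equality-constrained directed label.  The result is
#' returned both as the \code{vec}-ordered Jacobian \code{DG} (row
#' \code{t} of \code{vec(G)} is entry \code{G[t - k*floor((t-1)/k),
#' ceiling(t/k)]} with \code{k = nrow(G)}) and as a list of per-parameter
#' derivative matrices, together with the derivative of the fixed-
#' constant offset vector.  Entries are continuous in the directed
#' parameters.
#'
#' @inheritParams build_G
#' @return an object of class \code{snlls_dG}: \code{DG}
#'   (\code{nrow(G)*ncol(G) x dim(theta_Lambda)}), \code{dG_list},
#'   \code{d_offset} (\code{nrow(G) x dim(theta_Lambda)}) and the
#'   Jacobian's structural sparsity \code{pattern}.
#' @export
build_dG <- function(model, theta_lambda = numeric(0)) {
  ctx <- model_context(model)
  if (length(theta_lambda) != ctx$n_lam)
    stop_snllsem("theta_lambda has the wrong length", "snllsem_dim_error")
  B <- safe_binv(fill_lambda(model, theta_lambda))
  dBs <- dB_list(ctx, B)
  per <- lapply(dBs, function(dB) dG_ctx_n(ctx, B, dB))
  nr <- if (length(per)) nrow(per[[1]]$dG) else
    nrow(ctx$im$D) + if (ctx$has_mean) ctx$m_obs else 0L
  nc <- ctx$n_om + if (ctx$has_mean) ctx$n_gam else 0L
  DG <- matrix(0, nr * nc, ctx$n_lam)
  d_off <- matrix(0, nr, ctx$n_lam)
  for (n in seq_len(ctx$n_lam)) {
    DG[, n] <- as.vector(per[[n]]$dG)
    d_off[, n] <- per[[n]]$doffset
  }
  structure(list(DG = DG, dG_list = lapply(per, `[[`, "dG"),
                 d_offset = d_off, dims = c(nr, nc),
                 pattern = DG != 0),
            class = "snlls_dG")
}

#' Gradient of the reduced objective
#'
#' Exact gradient of \code{\link{reduced_objective}} with respect to the
#' directed parameters, assembled from the analytic Jacobian of G by the
#' chain rule.  Because the profiled linear parameters satisfy the
#' normal equations, the envelope theorem gives
#' \code{dF/d(theta_Lambda)_n = -2 r^T V (dG_n w + d offset_n)} with
#' \code{r} the residual and \code{w} the \code{\link{solve_linear}}
#' minimizer -- a form that remains valid under rank deficiency of
#' \code{G' V G} (locally constant rank), and is validated against
#' central finite differences.
#'
#' @inheritParams build_G
#' @param V an \code{snlls_weight} or weight matrix.
#' @param s observed moment vector.
#' @return numeric vector of length \code{dim(theta_Lambda)}.
#' @export
reduced_gradient <- function(model, theta_lambda, V, s) {
  ctx <- model_context(model)
  Vm <- weight_V(V)
  B <- safe_binv(fill_lambda(model, theta_lambda))
  parts <- build_G_ctx(ctx, B)
  st <- stack_G(ctx, parts)
  sh <- s - st$offset
  VG <- Vm %*% st$G
  w <- pinv_solve(crossprod(st$G, VG), drop(crossprod(VG, sh)))
  r <- sh - drop(st$G %*% w)
  vr <- drop(Vm %*% r)
  dBs <- dB_list(ctx, B)
  vapply(seq_len(ctx$n_lam), function(n) {
    dg <- dG_ctx_n(ctx, B, dBs[[n]])
    -2 * sum(vr * (drop(dg$dG %*% w) + dg$doffset))
  }, numeric(1))
}
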