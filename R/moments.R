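# Numeric model-implied moments and least squares weight matrices.
#
# Sigma(theta) = F (I - Lambda)^-1 Omega (I - Lambda)^-T F^T
# mu(theta)    = F (I - Lambda)^-1 gamma
#
# with F = [I | 0] selecting the observed variables.  The half-
# vectorization uses column-major order over the lower triangle,
# consistently with index_maps() and duplication_matrix().

#' Model-implied covariance matrix of the observed variables
#'
#' Evaluates the filtered congruence product
#' \code{F (I - Lambda)^-1 Omega (I - Lambda)^-T F^T} at a parameter
#' vector.  Invertibility of \code{I - Lambda} is guarded by a
#' reciprocal-condition-number check (below \code{1e-12} the matrix is
#' treated as singular and an error of class \code{snllsem_singular} is
#' raised, carrying no salvageable result).
#'
#' @param model a \code{ram_model}.
#' @param theta numeric parameter vector of length \code{n_par(model)}.
#' @return symmetric \code{m_obs x m_obs} matrix.
#' @export
implied_sigma <- function(model, theta) {
  mats <- materialize(model, theta)
  B <- safe_binv(mats$Lambda)
  S <- B %*% mats$Omega %*% t(B)
  S <- S[seq_len(model$m_obs), seq_len(model$m_obs), drop = FALSE]
  (S + t(S)) / 2
}

#' Model-implied means of the observed variables
#'
#' Evaluates \code{F (I - Lambda)^-1 gamma}.  Models without a declared
#' mean structure return a zero vector.
#'
#' @inheritParams implied_sigma
#' @return numeric vector of length \code{m_obs}.
#' @export
implied_mu <- function(model, theta) {
  mats <- materialize(model, theta)
  B <- safe_binv(mats$Lambda)
  drop(B %*% mats$gamma)[seq_len(model$m_obs)]
}

#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) in column-major
#' order: \code{(1,1), (2,1), ..., (m,1), (2,2), ...}.  This is the vech
#' convention used by every moment vector in the package.
#'
#' @param M a symmetric numeric matrix.
#' @return numeric vector of length \code{m(m+1)/2}.
#' @export
vech <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop_snllsem("vech requires a square matrix", "snllsem_dim_error")
  M[lower.tri(M, diag = TRUE)]
}

#' @rdname vech
#' @export
half_vectorize <- vech

#' Reconstruct a symmetric matrix from its half-vectorization
#' @param v numeric vector of length \code{m(m+1)/2}.
#' @return symmetric \code{m x m} matrix.
#' @rdname vech
#' @export
unvech <- function(v) {
  m <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(m - round(m)) > 1e-8)
    stop_snllsem("length is not m(m+1)/2 for any integer m", "snllsem_dim_error")
  m <- as.integer(round(m))
  M <- matrix(0, m, m)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M), m)
}

#' Duplication matrix
#'
#' The \code{m^2 x m(m+1)/2} binary matrix \code{D} (Magnus-Neudecker
#' convention, matched to this package's vech order) satisfying
#' \code{D \%*\% vech(M) == vec(M)} for every symmetric \code{M}.
#'
#' @param m integer dimension.
#' @return the duplication matrix.
#' @export
duplication_matrix <- function(m) {
  stopifnot(m >= 1)
  D <- matrix(0, m * m, m * (m + 1) / 2)
  col <- 0L
  for (j in seq_len(m)) for (i in seq.int(j, m)) {
    col <- col + 1L
    D[(j - 1L) * m + i, col] <- 1
    D[(i - 1L) * m + j, col] <- 1
  }
  D
}

#' Least squares weight matrices
#'
#' Builds the weight matrix of the covariance-structure least squares
#' discrepancy \code{(s - sigma)^T V (s - sigma)}:
#' \describe{
#'   \item{GLS}{\code{V = 1/2 D^T (S^-1 x S^-1) D} with \code{D} the
#'     duplication matrix; requires an invertible sample covariance
#'     \code{S}.}
#'   \item{ULS}{the identity matrix.}
#'   \item{user}{a validated pass-through of a user-supplied symmetric
#'     matrix.}
#' }
#' With \code{stacked = TRUE} (models with a mean structure) the weight
#' is block-diagonal over the covariance and mean residuals; the mean
#' block is \code{S^-1} for GLS and the identity for ULS, and may be
#' overridden via \code{V_mu}.
#'
#' @param kind one of \code{"gls"}, \code{"uls"}, \code{"user"}.
#' @param S sample covariance matrix (required for GLS; fixes the
#'   dimension otherwise if \code{m_obs} is missing).
#' @param m_obs number of observed variables (needed for ULS without
#'   \code{S}).
#' @param stacked add the mean block.
#' @param V user-supplied weight matrix (for \code{kind = "user"}; of
#'   stacked size when \code{stacked = TRUE}).
#' @param V_mu optional override of the mean-block weight.
#' @return an object of class \code{snlls_weight} with elements
#'   \code{kind}, \code{V}, \code{V_sigma}, \code{V_mu}, \code{stacked}.
#' @export
weight_matrix <- function(kind = c("gls", "uls", "user"), S = NULL,
                          m_obs = NULL, stacked = FALSE, V = NULL,
                          V_mu = NULL) {
  kind <- match.arg(kind)
  m <- if (!is.null(S)) nrow(S) else m_obs
  if (is.null(m) && kind != "user")
    stop_snllsem("need S or m_obs to size the weight matrix", "snllsem_dim_error")

  if (kind == "gls") {
    if (is.null(S)) stop_snllsem("GLS requires a sample covariance S", "snllsem_weight_error")
    if (!is_symmetric_num(S))
      stop_snllsem("sample covariance S is not symmetric", "snllsem_weight_error")
    if (rcond(S) < 1e-14)
      stop_snllsem("sample covariance S is (numerically) singular; GLS weight undefined",
                   "snllsem_weight_error")
    Sinv <- solve(S)
    Dm <- duplication_matrix(m)
    Vs <- 0.5 * crossprod(Dm, (Sinv %x% Sinv) %*% Dm)
    Vs <- (Vs + t(Vs)) / 2
    Vm <- V_mu %||% Sinv
  } else if (kind == "uls") {
    Vs <- diag(m * (m + 1) / 2)
    Vm <- V_mu %||% diag(m)
  } else {
    if (is.null(V)) stop_snllsem("kind = 'user' requires V", "snllsem_weight_error")
    if (!is_symmetric_num(V))
      stop_snllsem("user weight matrix is not symmetric", "snllsem_weight_error")
    if (stacked) {
      if (is.null(m))
        stop_snllsem("need S or m_obs to split a stacked user weight", "snllsem_dim_error")
      nD <- m * (m + 1) / 2
      if (nrow(V) != nD + m)
        stop_snllsem("stacked user weight has the wrong dimension", "snllsem_dim_error")
      Vs <- V[seq_len(nD), seq_len(nD), drop = FALSE]
      Vm <- V[nD + seq_len(m), nD + seq_len(m), drop = FALSE]
    } else {
      Vs <- V
      Vm <- V_mu
    }
  }
  full <- if (stacked) block_diag(Vs, Vm) else Vs
  structure(list(kind = kind, V = full, V_sigma = Vs, V_mu = Vm,
                 stacked = stacked),
            class = "snlls_weight")
}

weight_V <- function(V) {
  if (inherits(V, "snlls_weight")) V$V else V
}

#' Sample moments from raw data
#'
#' Computes the sample covariance matrix (with denominator \code{N} by
#' default, switchable to \code{N - 1}), the sample means, and the
#' sample size from a rectangular data table (rows = cases, columns =
#' observed variables).
#'
#' @param data a numeric matrix or data frame.
#' @param denominator \code{"N"} (default) or \code{"N-1"}.
#' @return list with \code{S}, \code{N}, \code{means}.
#' @export
sample_moments <- function(data, denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  X <- as.matrix(data)
  if (!is.numeric(X)) stop_snllsem("data must be numeric", "snllsem_data_error")
  N <- nrow(X)
  if (N < 2L) stop_snllsem("need at least two rows to form a covariance matrix",
                           "snllsem_data_error")
  S <- stats::cov(X)
  if (denominator == "N") S <- S * (N - 1) / N
  list(S = S, N = N, means = colMeans(X))
}
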