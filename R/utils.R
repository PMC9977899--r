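# internal helpers shared across modules

stop_snllsem <- function(msg, class, ...) {
  stop(structure(class = c(class, "snllsem_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_syntax <- function(line, msg) {
  stop_snllsem(sprintf("model syntax error on line %d: %s", line, msg),
               "snllsem_syntax_error", line = line)
}

is_symmetric_num <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

block_diag <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  if (nrow(A)) out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  if (nrow(B)) out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

# Moore-Penrose solve of the (symmetric PSD) normal matrix M against b;
# singular values below rtol * max(d) are treated as exact zeros.
pinv_solve <- function(M, b, rtol = 1e-10) {
  if (ncol(M) == 0L) return(numeric(0))
  if (any(!is.finite(M)) || any(!is.finite(b)))
    stop_snllsem("non-finite values in linear solve", "snllsem_nonfinite")
  sv <- svd(M)
  keep <- sv$d > rtol * max(sv$d[1], 0)
  if (!any(keep)) return(numeric(ncol(M)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep]))
}

# inverse of (I - Lambda) with a reciprocal-condition-number guard
safe_binv <- function(Lambda, rcond_tol = 1e-12) {
  IL <- diag(nrow(Lambda)) - Lambda
  if (any(!is.finite(IL)) || rcond(IL) < rcond_tol)
    stop_snllsem("I - Lambda is (numerically) singular at the supplied parameters",
                 "snllsem_singular")
  solve(IL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
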