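# Trek-rule path tracing on the model's mixed graph.
#
# A trek between i and j is a walk without colliding arrowheads: a
# directed path from an anchor into i (traversed backwards), followed by
# either nothing (the anchor is the trek's top node, whose variance is
# factored in) or a bidirected covariance edge, followed by a directed
# path to j.  Summing all trek monomials yields the model-implied
# covariance between i and j -- an independent, purely graphical route to
# the same quantity the matrix pipeline computes, used here as a
# cross-validation oracle.  Each monomial contains exactly one undirected
# factor because error covariances are not transitive.
#
# Enumeration requires the directed part to be acyclic (a cyclic graph
# has infinitely many treks); the matrix pipeline stays available for
# cyclic models.

#' Mixed graph of a RAM model
#'
#' Extracts the model's mixed graph: directed edges \code{k -> l}
#' carrying the symbol \code{lambda_lk} (the parameter label, or a fixed
#' constant), plus variance entries and bidirected covariance edges from
#' Omega.  Variances are not edges -- they cannot be traveled -- but they
#' anchor top-node treks.  Entries fixed at exactly zero are dropped.
#'
#' @param model a \code{ram_model}.
#' @return an object of class \code{mixed_graph}.
#' @export
mixed_graph <- function(model) {
  nodes <- model$nodes
  lam <- model$lambda
  directed <- data.frame(from = nodes[lam$j], to = nodes[lam$i],
                         label = lam$label, value = lam$value,
                         stringsAsFactors = FALSE)
  directed <- directed[!(is.na(directed$label) & directed$value == 0), , drop = FALSE]
  om <- model$omega
  keep <- is.na(om$value) | om$value != 0
  om <- om[keep, , drop = FALSE]
  vr <- om[om$i == om$j, , drop = FALSE]
  cv <- om[om$i != om$j, , drop = FALSE]
  variances <- data.frame(node = nodes[vr$i], label = vr$label,
                          value = vr$value, stringsAsFactors = FALSE)
  covariances <- data.frame(a = nodes[cv$i], b = nodes[cv$j],
                            label = cv$label, value = cv$value,
                            stringsAsFactors = FALSE)
  structure(list(nodes = nodes, directed = directed,
                 variances = variances, covariances = covariances),
            class = "mixed_graph")
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat("mixed graph:", length(x$nodes), "nodes,", nrow(x$directed),
      "directed edges,", nrow(x$covariances), "covariance edges,",
      nrow(x$variances), "variances\n")
  invisible(x)
}

graph_acyclic <- function(graph) {
  idx <- stats::setNames(seq_along(graph$nodes), graph$nodes)
  m <- length(graph$nodes)
  from <- idx[graph$directed$from]; to <- idx[graph$directed$to]
  indeg <- tabulate(to, m)
  queue <- which(indeg == 0L); removed <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    for (h in to[from == v]) {
      indeg[h] <- indeg[h] - 1L
      if (indeg[h] == 0L) queue <- c(queue, h)
    }
  }
  removed == m
}

assert_acyclic <- function(graph) {
  if (!graph_acyclic(graph))
    stop_snllsem(paste("the directed part of the graph contains a cycle;",
                       "the set of treks may be infinite and enumeration is refused"),
                 "snllsem_cyclic")
}

# all directed paths from `from` to `to`, as node-name vectors (acyclic
# graph assumed; from == to yields the empty path c(from))
all_directed_paths <- function(graph, from, to) {
  paths <- list()
  ed <- graph$directed
  walk <- function(cur, acc) {
    acc <- c(acc, cur)
    if (cur == to) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())   # on a DAG no path can leave `to` and return
    }
    for (nxt in ed$to[ed$from == cur]) walk(nxt, acc)
  }
  if (from %in% graph$nodes && to %in% graph$nodes) walk(from, character())
  paths
}

new_trek <- function(source, target, kind, anchor, left, right) {
  nodes <- if (kind == "top") c(rev(left), right[-1]) else c(rev(left), right)
  structure(list(source = source, target = target, kind = kind,
                 anchor = anchor, left = left, right = right,
                 nodes = nodes),
            class = "trek")
}

#' @export
print.trek <- function(x, ...) {
  if (x$kind == "top") {
    cat(paste(x$nodes, collapse = " - "),
        sprintf("  [top node %s]\n", x$anchor[1]))
  } else {
    k <- length(x$left)
    cat(paste(c(x$nodes[seq_len(k)], "<->", x$nodes[-seq_len(k)]), collapse = " - "),
        sprintf("  [covariance %s~~%s]\n", x$anchor[1], x$anchor[2]))
  }
  invisible(x)
}

#' Enumerate all treks between two nodes
#'
#' Treks factor as a directed path from an anchor into the source
#' (traversed backwards), the anchor itself (a top node with a variance,
#' or a covariance edge), and a directed path from the anchor to the
#' target.  On an acyclic directed part this factorization is finite and
#' is enumerated exhaustively; the result is duplicate-free and sorted
#' lexicographically by node sequence.  Treks are ordered: a trek from
#' \code{j} to \code{i} with the same edges is a different trek.
#'
#' @param graph a \code{mixed_graph} (or a \code{ram_model}, converted on
#'   the fly).
#' @param i,j source and target node names.
#' @return list of \code{trek} objects.
#' @export
enumerate_treks <- function(graph, i, j) {
  if (inherits(graph, "ram_model")) graph <- mixed_graph(graph)
  assert_acyclic(graph)
  if (!all(c(i, j) %in% graph$nodes))
    stop_snllsem("unknown node name", "snllsem_node_error")
  treks <- list()
  add <- function(tr) treks[[length(treks) + 1L]] <<- tr

  for (a in graph$variances$node) {
    L <- all_directed_paths(graph, a, i)
    R <- all_directed_paths(graph, a, j)
    for (l in L) for (r in R) add(new_trek(i, j, "top", a, l, r))
  }
  if (nrow(graph$covariances)) {
    for (e in seq_len(nrow(graph$covariances))) {
      a <- graph$covariances$a[e]; b <- graph$covariances$b[e]
      for (pair in list(c(a, b), c(b, a))) {
        L <- all_directed_paths(graph, pair[1], i)
        R <- all_directed_paths(graph, pair[2], j)
        for (l in L) for (r in R) add(new_trek(i, j, "cov", pair, l, r))
      }
    }
  }
  keys <- vapply(treks, function(tr)
    paste(c(tr$nodes, "|", tr$kind, tr$anchor), collapse = "\r"), character(1))
  treks[order(keys)]
}

edge_factor <- function(graph, from, to) {
  ed <- graph$directed
  hit <- which(ed$from == from & ed$to == to)
  if (!length(hit))
    stop_snllsem(sprintf("no directed edge %s -> %s", from, to), "snllsem_node_error")
  list(label = ed$label[hit[1]], value = ed$value[hit[1]])
}

new_monomial <- function(coef, omega, lambda) {
  structure(list(coef = coef, omega = omega, lambda = sort(lambda)),
            class = "trek_monomial")
}

#' Trek monomial of a trek
#'
#' Multiplies the directed-edge symbols \code{lambda_lk} along the trek
#' (indices swapped relative to the edge direction \code{k -> l}) and
#' factors in exactly one undirected symbol: the variance
#' \code{omega_{i0 i0}} of the top node, or the covariance
#' \code{omega_{i0 j0}} of the trek's bidirected edge.  Fixed numeric
#' constants are folded into the monomial coefficient.
#'
#' @param trek a \code{trek}.
#' @param graph the \code{mixed_graph} the trek was enumerated on.
#' @return an object of class \code{trek_monomial} with fields
#'   \code{coef}, \code{omega} (symbol or \code{NA} if the undirected
#'   entry is a fixed constant) and \code{lambda} (sorted character
#'   vector of directed symbols).
#' @export
trek_monomial <- function(trek, graph) {
  if (inherits(graph, "ram_model")) graph <- mixed_graph(graph)
  coef <- 1; lambda <- character()
  take_path <- function(p) {
    if (length(p) < 2L) return(invisible())
    for (t in seq_len(length(p) - 1L)) {
      f <- edge_factor(graph, p[t], p[t + 1L])
      if (is.na(f$label)) coef <<- coef * f$value
      else lambda <<- c(lambda, f$label)
    }
  }
  take_path(trek$left)
  take_path(trek$right)
  if (trek$kind == "top") {
    vr <- graph$variances
    hit <- which(vr$node == trek$anchor[1])[1]
    om <- vr$label[hit]; omv <- vr$value[hit]
  } else {
    cv <- graph$covariances
    hit <- which((cv$a == trek$anchor[1] & cv$b == trek$anchor[2]) |
                   (cv$a == trek$anchor[2] & cv$b == trek$anchor[1]))[1]
    om <- cv$label[hit]; omv <- cv$value[hit]
  }
  if (is.na(om)) { coef <- coef * omv; om <- NA_character_ }
  new_monomial(coef, om, lambda)
}

# canonical polynomial: monomials merged on (omega, lambda multiset),
# sorted by their printed key
canonical_poly <- function(monomials) {
  if (!length(monomials))
    return(structure(list(), class = "trek_poly"))
  keys <- vapply(monomials, function(mn)
    paste(c(mn$omega %||% NA, mn$lambda), collapse = "\r"), character(1))
  out <- list()
  for (k in unique(sort(keys))) {
    grp <- monomials[keys == k]
    mn <- grp[[1]]
    mn$coef <- sum(vapply(grp, `[[`, numeric(1), "coef"))
    out[[length(out) + 1L]] <- mn
  }
  structure(out, class = "trek_poly")
}

format_monomial <- function(mn) {
  syms <- sort(c(mn$lambda, if (!is.na(mn$omega)) mn$omega))
  if (!length(syms)) return(format(mn$coef))
  if (mn$coef == 1) paste(syms, collapse = "*")
  else paste(c(format(mn$coef), syms), collapse = "*")
}

#' @export
format.trek_poly <- function(x, ...) {
  if (!length(x)) return("0")
  paste(vapply(x, format_monomial, character(1)), collapse = " + ")
}

#' @export
print.trek_poly <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
format.trek_monomial <- function(x, ...) format_monomial(x)

#' @export
print.trek_monomial <- function(x, ...) { cat(format_monomial(x), "\n"); invisible(x) }

#' Evaluate a trek polynomial at parameter values
#'
#' @param poly a \code{trek_poly}.
#' @param bindings named numeric vector mapping every symbol appearing in
#'   the polynomial to a value.
#' @return a number.
#' @export
eval_poly <- function(poly, bindings) {
  tot <- 0
  for (mn in poly) {
    syms <- c(mn$lambda, if (!is.na(mn$omega)) mn$omega)
    miss <- setdiff(syms, names(bindings))
    if (length(miss))
      stop_snllsem(sprintf("no binding for symbol '%s'", miss[1]),
                   "snllsem_binding_error")
    tot <- tot + mn$coef * prod(bindings[syms])
  }
  tot
}

poly_equal <- function(a, b, tol = 1e-12) {
  fa <- format(a); fb <- format(b)
  identical(fa, fb) ||
    (length(a) == length(b) &&
       all(mapply(function(x, y)
         identical(x$omega, y$omega) && identical(x$lambda, y$lambda) &&
           abs(x$coef - y$coef) <= tol, a, b)))
}

#' Model-implied covariance via trek rules
#'
#' Sums the trek monomials over all treks between \code{i} and \code{j},
#' yielding the implied covariance as a polynomial in the parameter
#' symbols -- or, with \code{bindings}, as a number.  This is the
#' symbolic oracle against which the matrix formula
#' \code{F (I-Lambda)^-1 Omega (I-Lambda)^-T F'} is cross-validated.
#'
#' @inheritParams enumerate_treks
#' @param bindings optional named numeric vector of parameter values.
#' @return a \code{trek_poly}, or a number when \code{bindings} is given.
#' @export
implied_cov_trek <- function(graph, i, j, bindings = NULL) {
  if (inherits(graph, "ram_model")) graph <- mixed_graph(graph)
  treks <- enumerate_treks(graph, i, j)
  poly <- canonical_poly(lapply(treks, trek_monomial, graph = graph))
  if (is.null(bindings)) poly else eval_poly(poly, bindings)
}

#' Entries of the inverse of I - Lambda as path sums
#'
#' \code{(I - Lambda)^-1[i, j]} equals the sum over directed paths from
#' \code{j} to \code{i} of the product of edge symbols (the geometric
#' series of Lambda, term by term); \code{i == j} gives 1 (the empty
#' path).
#'
#' @inheritParams enumerate_treks
#' @param bindings optional named numeric vector of parameter values.
#' @return a \code{trek_poly}, or a number when \code{bindings} is given.
#' @export
path_sum_inverse <- function(graph, j, i, bindings = NULL) {
  if (inherits(graph, "ram_model")) graph <- mixed_graph(graph)
  assert_acyclic(graph)
  paths <- all_directed_paths(graph, j, i)
  mono <- lapply(paths, function(p) {
    coef <- 1; lambda <- character()
    if (length(p) > 1L) for (t in seq_len(length(p) - 1L)) {
      f <- edge_factor(graph, p[t], p[t + 1L])
      if (is.na(f$label)) coef <- coef * f$value
      else lambda <- c(lambda, f$label)
    }
    new_monomial(coef, NA_character_, lambda)
  })
  poly <- canonical_poly(mono)
  if (is.null(bindings)) poly else eval_poly(poly, bindings)
}
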