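# RAM model representation: patterned matrices Lambda (directed effects),
# Omega (symmetric undirected (co)variances), gamma (means), with the
# observed variables ordered first so that the filter is F = [I | 0].
#
# Patterns are stored as triplet data frames; a row carries either a free
# parameter label (label != NA) or a fixed numeric constant (label == NA).
# A label repeated within a block is an equality constraint; reuse across
# blocks is rejected.

.name_rx <- "[A-Za-z._][A-Za-z0-9._]*"

new_ram_model <- function(nodes, m_obs, m_lat, lambda, omega, gamma,
                          par_lambda, par_omega, par_gamma) {
  structure(list(nodes = nodes, m_obs = m_obs, m_lat = m_lat,
                 lambda = lambda, omega = omega, gamma = gamma,
                 par_lambda = par_lambda, par_omega = par_omega,
                 par_gamma = par_gamma),
            class = "ram_model")
}

# parse the `[label | = const]` tail of an edge / mean statement
parse_value_tail <- function(tokens, line, default_label) {
  tail <- trimws(paste(tokens, collapse = " "))
  if (tail == "")
    return(list(label = default_label, value = NA_real_))
  if (startsWith(tail, "=")) {
    num <- suppressWarnings(as.numeric(trimws(sub("^=", "", tail))))
    if (length(num) != 1L || is.na(num))
      stop_syntax(line, "expected a numeric constant after '='")
    return(list(label = NA_character_, value = num))
  }
  if (!grepl(paste0("^", .name_rx, "$"), tail)) {
    if (grepl("^[-+0-9.]", tail))
      stop_syntax(line, "fixed values must be written as '= value'")
    stop_syntax(line, sprintf("invalid parameter label '%s'", tail))
  }
  list(label = tail, value = NA_real_)
}

#' Parse a RAM model specification from text
#'
#' Reads the plain-text model syntax, one statement per line:
#' \describe{
#'   \item{\code{latent: l1 l2}}{declares latent variables (all other
#'     variable names are observed).}
#'   \item{\code{a -> b [label | = const]}}{a directed edge (regression
#'     path or factor loading) from \code{a} to \code{b}; a bare label
#'     makes it a free parameter, \code{= const} fixes it, and omitting
#'     both auto-labels it \code{"b~a"}.}
#'   \item{\code{a <-> b [label | = const]}}{an undirected edge: the
#'     (co)variance of the error terms of \code{a} and \code{b}
#'     (\code{a <-> a} is a variance); auto-label \code{"a~~b"}.}
#'   \item{\code{mean: a [label | = const]}}{a mean/intercept term;
#'     auto-label \code{"a~1"}.}
#' }
#' Comments start with \code{#}.  Reusing a label within a block imposes
#' an equality constraint; reusing it across blocks is an error.
#'
#' Nodes are ordered observed-first (in order of first appearance), then
#' latent (in declaration order), so the filter matrix selecting observed
#' variables is \code{[I | 0]} by construction.  Parameters are ordered
#' directed first, then undirected, then means, each by first appearance;
#' this ordering is used by every parameter vector in the package.
#'
#' @param text character; the model syntax (single string or vector of
#'   lines).
#' @return an object of class \code{ram_model}.
#' @seealso [materialize()], [index_maps()], [validate_model()]
#' @examples
#' m <- parse_model("
#'   latent: l
#'   l -> x1 = 1
#'   l -> x2 = 1
#'   x1 <-> x1 omega1
#'   x2 <-> x2 omega2
#'   l  <-> l  omega_l")
#' m
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text))
  raw <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  code <- trimws(sub("#.*$", "", raw))

  latent <- character()
  stmts <- list()
  for (ln in seq_along(code)) {
    s <- code[ln]
    if (s == "") next
    if (grepl("^latent\\s*:", s)) {
      nm <- strsplit(trimws(sub("^latent\\s*:", "", s)), "\\s+")[[1]]
      nm <- nm[nzchar(nm)]
      if (!length(nm) || !all(grepl(paste0("^", .name_rx, "$"), nm)))
        stop_syntax(ln, "expected 'latent: name1 name2 ...'")
      dup <- nm[nm %in% latent | duplicated(nm)]
      if (length(dup))
        stop_syntax(ln, sprintf("latent variable '%s' declared twice", dup[1]))
      latent <- c(latent, nm)
    } else {
      stmts[[length(stmts) + 1L]] <- list(line = ln, text = s)
    }
  }

  seen <- character()
  note_node <- function(nm) seen <<- c(seen, setdiff(nm, seen))
  check_node <- function(nm, ln) {
    bad <- nm[!grepl(paste0("^", .name_rx, "$"), nm)]
    if (length(bad))
      stop_syntax(ln, sprintf("invalid variable name '%s'", bad[1]))
  }

  edges_l <- list(); edges_o <- list(); means <- list()
  for (st in stmts) {
    s <- st$text; ln <- st$line
    if (grepl("^mean\\s*:", s)) {
      parts <- strsplit(trimws(sub("^mean\\s*:", "", s)), "\\s+")[[1]]
      parts <- parts[nzchar(parts)]
      if (!length(parts)) stop_syntax(ln, "expected 'mean: node [label | = const]'")
      node <- parts[1]; check_node(node, ln); note_node(node)
      pv <- parse_value_tail(parts[-1], ln, paste0(node, "~1"))
      means[[length(means) + 1L]] <-
        list(node = node, label = pv$label, value = pv$value, line = ln)
    } else if (grepl("<->", s, fixed = TRUE)) {
      two <- strsplit(s, "<->", fixed = TRUE)[[1]]
      if (length(two) != 2L) stop_syntax(ln, "expected 'a <-> b [label | = const]'")
      a <- trimws(two[1])
      rhs <- strsplit(trimws(two[2]), "\\s+")[[1]]
      rhs <- rhs[nzchar(rhs)]
      if (!nzchar(a) || !length(rhs))
        stop_syntax(ln, "expected 'a <-> b [label | = const]'")
      b <- rhs[1]
      check_node(c(a, b), ln); note_node(c(a, b))
      pv <- parse_value_tail(rhs[-1], ln, paste0(a, "~~", b))
      edges_o[[length(edges_o) + 1L]] <-
        list(a = a, b = b, label = pv$label, value = pv$value, line = ln)
    } else if (grepl("->", s, fixed = TRUE)) {
      two <- strsplit(s, "->", fixed = TRUE)[[1]]
      if (length(two) != 2L) stop_syntax(ln, "expected 'a -> b [label | = const]'")
      a <- trimws(two[1])
      rhs <- strsplit(trimws(two[2]), "\\s+")[[1]]
      rhs <- rhs[nzchar(rhs)]
      if (!nzchar(a) || !length(rhs))
        stop_syntax(ln, "expected 'a -> b [label | = const]'")
      b <- rhs[1]
      check_node(c(a, b), ln); note_node(c(a, b))
      pv <- parse_value_tail(rhs[-1], ln, paste0(b, "~", a))
      edges_l[[length(edges_l) + 1L]] <-
        list(from = a, to = b, label = pv$label, value = pv$value, line = ln)
    } else {
      stop_syntax(ln, sprintf("unrecognized statement '%s'", s))
    }
  }

  unused_latent <- setdiff(latent, seen)
  observed <- setdiff(seen, latent)
  nodes <- c(observed, latent[latent %in% seen], unused_latent)
  m_obs <- length(observed)
  m_lat <- length(latent)
  if (m_obs == 0L)
    stop_snllsem("model declares no observed variables", "snllsem_model_error")
  idx <- stats::setNames(seq_along(nodes), nodes)

  # Lambda triplets: edge from -> to lives at Lambda[to, from]
  lam <- data.frame(i = integer(), j = integer(),
                    label = character(), value = numeric())
  for (e in edges_l) {
    i <- idx[[e$to]]; j <- idx[[e$from]]
    if (i == j) stop_syntax(e$line, sprintf("self-loop '%s -> %s'", e$from, e$to))
    if (any(lam$i == i & lam$j == j))
      stop_syntax(e$line, sprintf("duplicate directed edge '%s -> %s'", e$from, e$to))
    lam <- rbind(lam, data.frame(i = i, j = j, label = e$label, value = e$value))
  }

  # Omega triplets, stored once per pair on the lower triangle (i >= j)
  om <- data.frame(i = integer(), j = integer(),
                   label = character(), value = numeric())
  for (e in edges_o) {
    i <- max(idx[[e$a]], idx[[e$b]]); j <- min(idx[[e$a]], idx[[e$b]])
    if (any(om$i == i & om$j == j))
      stop_syntax(e$line, sprintf("duplicate undirected edge '%s <-> %s'", e$a, e$b))
    om <- rbind(om, data.frame(i = i, j = j, label = e$label, value = e$value))
  }

  ga <- data.frame(i = integer(), label = character(), value = numeric())
  for (e in means) {
    i <- idx[[e$node]]
    if (any(ga$i == i))
      stop_syntax(e$line, sprintf("duplicate mean term for '%s'", e$node))
    ga <- rbind(ga, data.frame(i = i, label = e$label, value = e$value))
  }

  par_lambda <- unique(lam$label[!is.na(lam$label)])
  par_omega  <- unique(om$label[!is.na(om$label)])
  par_gamma  <- unique(ga$label[!is.na(ga$label)])
  blocks <- list(directed = par_lambda, undirected = par_omega, mean = par_gamma)
  for (b1 in seq_along(blocks)) for (b2 in seq_along(blocks)) {
    if (b1 >= b2) next
    shared <- intersect(blocks[[b1]], blocks[[b2]])
    if (length(shared))
      stop_snllsem(sprintf(
        "parameter label '%s' is used in both the %s and the %s block",
        shared[1], names(blocks)[b1], names(blocks)[b2]),
        "snllsem_label_error")
  }

  new_ram_model(nodes, m_obs, m_lat, lam, om, ga,
                par_lambda, par_omega, par_gamma)
}

#' @export
print.ram_model <- function(x, ...) {
  cat("RAM model:", x$m_obs, "observed +", x$m_lat, "latent variables\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  cat(sprintf("  free parameters: %d directed, %d undirected, %d mean\n",
              length(x$par_lambda), length(x$par_omega), length(x$par_gamma)))
  invisible(x)
}

#' Number and names of free parameters
#'
#' The flat parameter vector is ordered directed parameters first, then
#' undirected, then means, each in first-appearance order.
#'
#' @param model a \code{ram_model}.
#' @return \code{theta_names()}: character vector of labels;
#'   \code{n_par()}: its length.
#' @export
theta_names <- function(model) {
  c(model$par_lambda, model$par_omega, model$par_gamma)
}

#' @rdname theta_names
#' @export
n_par <- function(model) length(theta_names(model))

split_theta <- function(model, theta) {
  nl <- length(model$par_lambda); no <- length(model$par_omega)
  ng <- length(model$par_gamma)
  if (length(theta) != nl + no + ng)
    stop_snllsem(sprintf("theta has length %d, expected %d",
                         length(theta), nl + no + ng), "snllsem_dim_error")
  list(lambda = stats::setNames(theta[seq_len(nl)], model$par_lambda),
       omega  = stats::setNames(theta[nl + seq_len(no)], model$par_omega),
       gamma  = stats::setNames(theta[nl + no + seq_len(ng)], model$par_gamma))
}

fill_lambda <- function(model, theta_lambda) {
  m <- length(model$nodes)
  L <- matrix(0, m, m, dimnames = list(model$nodes, model$nodes))
  tl <- model$lambda
  if (nrow(tl)) {
    fixed <- is.na(tl$label)
    L[cbind(tl$i[fixed], tl$j[fixed])] <- tl$value[fixed]
    if (any(!fixed))
      L[cbind(tl$i[!fixed], tl$j[!fixed])] <-
        theta_lambda[match(tl$label[!fixed], model$par_lambda)]
  }
  L
}

#' Materialize the model matrices at a parameter vector
#'
#' Places fixed constants and free-parameter values into the directed
#' effect matrix Lambda, the symmetric undirected (co)variance matrix
#' Omega, and the mean vector gamma.  A label constrained to several
#' positions receives the same value in all of them, and Omega is exactly
#' symmetric by construction.
#'
#' @param model a \code{ram_model}.
#' @param theta numeric vector of length \code{n_par(model)} in the
#'   canonical parameter order.
#' @return list with components \code{Lambda} (m x m), \code{Omega}
#'   (m x m, symmetric) and \code{gamma} (length m).
#' @export
materialize <- function(model, theta) {
  th <- split_theta(model, theta)
  if (any(!is.finite(theta)))
    stop_snllsem("non-finite parameter values", "snllsem_nonfinite")
  m <- length(model$nodes)
  L <- fill_lambda(model, th$lambda)
  O <- matrix(0, m, m, dimnames = list(model$nodes, model$nodes))
  to <- model$omega
  if (nrow(to)) {
    val <- ifelse(is.na(to$label), to$value,
                  th$omega[match(to$label, model$par_omega)])
    O[cbind(to$i, to$j)] <- val
    O[cbind(to$j, to$i)] <- val
  }
  g <- stats::setNames(numeric(m), model$nodes)
  tg <- model$gamma
  if (nrow(tg))
    g[tg$i] <- ifelse(is.na(tg$label), tg$value,
                      th$gamma[match(tg$label, model$par_gamma)])
  list(Lambda = L, Omega = O, gamma = g)
}

#' Index maps of the free parameters and observed moments
#'
#' Computes the position tuples used throughout the package:
#' \describe{
#'   \item{\code{C}}{for each undirected parameter, the matrix of its
#'     lower-triangular positions \code{(l, k)} in Omega, \code{l >= k}
#'     (several rows for an equality-constrained label).}
#'   \item{\code{D}}{the positions \code{(i, j)}, \code{i >= j}, of the
#'     half-vectorization elements in the observed covariance matrix, in
#'     column-major order over the lower triangle.}
#'   \item{\code{E}}{for each directed parameter, its positions
#'     \code{(i, j)} in Lambda.}
#'   \item{\code{A}}{for each mean parameter, its indices in gamma.}
#' }
#'
#' @param model a \code{ram_model}.
#' @return an object of class \code{ram_index_maps}.
#' @export
index_maps <- function(model) {
  m <- model$m_obs
  jj <- unlist(lapply(seq_len(m), function(j) rep(j, m - j + 1L)))
  ii <- unlist(lapply(seq_len(m), function(j) seq.int(j, m)))
  D <- cbind(i = ii, j = jj)

  C <- lapply(model$par_omega, function(lb) {
    rows <- model$omega[!is.na(model$omega$label) & model$omega$label == lb, ]
    cbind(l = rows$i, k = rows$j)
  })
  names(C) <- model$par_omega

  E <- lapply(model$par_lambda, function(lb) {
    rows <- model$lambda[!is.na(model$lambda$label) & model$lambda$label == lb, ]
    cbind(i = rows$i, j = rows$j)
  })
  names(E) <- model$par_lambda

  A <- lapply(model$par_gamma, function(lb)
    model$gamma$i[!is.na(model$gamma$label) & model$gamma$label == lb])
  names(A) <- model$par_gamma

  structure(list(C = C, D = D, E = E, A = A, n_sigma = nrow(D)),
            class = "ram_index_maps")
}

# directed-part adjacency (over all Lambda entries, fixed or free):
# has_cycle via Kahn's algorithm
directed_cycle <- function(model) {
  m <- length(model$nodes)
  if (!nrow(model$lambda)) return(FALSE)
  # edge j -> i for every Lambda[i, j] entry
  from <- model$lambda$j; to <- model$lambda$i
  indeg <- tabulate(to, m)
  queue <- which(indeg == 0L)
  removed <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    heads <- to[from == v]
    for (h in heads) {
      indeg[h] <- indeg[h] - 1L
      if (indeg[h] == 0L) queue <- c(queue, h)
    }
  }
  removed < m
}

#' Validate a RAM model
#'
#' Produces a diagnostics report (never an error): whether the directed
#' part contains a cycle (in which case invertibility of \code{I -
#' Lambda} must be checked numerically at each parameter value), a free
#' parameter count against the number of observed moments (a crude
#' identification heuristic), unreferenced nodes, and source nodes whose
#' error variance is structurally zero.
#'
#' @param model a \code{ram_model}.
#' @return an object of class \code{ram_validation}; a list with fields
#'   \code{cycle}, \code{n_free}, \code{n_moments}, \code{saturated},
#'   \code{overparameterized}, \code{unreferenced},
#'   \code{zero_variance_sources} and \code{notes}.
#' @export
validate_model <- function(model) {
  n_free <- n_par(model)
  n_moments <- model$m_obs * (model$m_obs + 1L) / 2L +
    if (nrow(model$gamma)) model$m_obs else 0L
  cyc <- directed_cycle(model)

  used <- sort(unique(c(model$lambda$i, model$lambda$j,
                        model$omega$i, model$omega$j, model$gamma$i)))
  unreferenced <- model$nodes[setdiff(seq_along(model$nodes), used)]

  has_incoming <- unique(model$lambda$i)
  diag_rows <- model$omega[model$omega$i == model$omega$j, ]
  has_var <- diag_rows$i[is.na(diag_rows$value) | diag_rows$value != 0]
  zero_src <- setdiff(seq_along(model$nodes), union(has_incoming, has_var))
  zero_src <- model$nodes[zero_src]

  notes <- character()
  if (cyc) notes <- c(notes, "directed cycle present: check I - Lambda numerically at each theta")
  if (n_free == n_moments) notes <- c(notes, "saturated: free parameters equal observed moments")
  if (n_free > n_moments) notes <- c(notes, "more free parameters than observed moments: not identified")
  if (length(unreferenced))
    notes <- c(notes, paste("unreferenced nodes:", paste(unreferenced, collapse = ", ")))
  if (length(zero_src))
    notes <- c(notes, paste("source nodes with structurally zero variance:",
                            paste(zero_src, collapse = ", ")))

  structure(list(cycle = cyc, n_free = n_free, n_moments = n_moments,
                 saturated = n_free == n_moments,
                 overparameterized = n_free > n_moments,
                 unreferenced = unreferenced,
                 zero_variance_sources = zero_src,
                 notes = notes),
            class = "ram_validation")
}

#' @export
print.ram_validation <- function(x, ...) {
  cat(sprintf("free parameters: %d, observed moments: %d\n", x$n_free, x$n_moments))
  if (length(x$notes)) cat(paste0("  - ", x$notes, collapse = "\n"), "\n")
  else cat("  no findings\n")
  invisible(x)
}

#' Serialize a RAM model to/from JSON
#'
#' The patterns are written as sparse triplet lists, preserving node and
#' parameter order, so that \code{ram_from_json(ram_to_json(m))}
#' reproduces \code{m} exactly.
#'
#' @param model a \code{ram_model}.
#' @param json a JSON string produced by \code{ram_to_json}.
#' @return \code{ram_to_json()}: a JSON string; \code{ram_from_json()}: a
#'   \code{ram_model}.
#' @export
ram_to_json <- function(model) {
  jsonlite::toJSON(list(
    nodes = model$nodes, m_obs = model$m_obs, m_lat = model$m_lat,
    lambda = model$lambda, omega = model$omega, gamma = model$gamma,
    par_lambda = model$par_lambda, par_omega = model$par_omega,
    par_gamma = model$par_gamma),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "list")
}

#' @rdname ram_to_json
#' @export
ram_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  as_trip <- function(df, cols) {
    df <- as.data.frame(df)
    if (!nrow(df)) {
      df <- as.data.frame(stats::setNames(
        lapply(cols, function(cl)
          if (cl %in% c("i", "j")) integer() else
            if (cl == "label") character() else numeric()), cols))
    }
    for (cl in intersect(c("i", "j"), cols)) df[[cl]] <- as.integer(df[[cl]])
    df$label <- as.character(df$label)
    df$value <- as.numeric(df$value)
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
    df
  }
  new_ram_model(unlist(x$nodes), x$m_obs, x$m_lat,
                as_trip(x$lambda, c("i", "j", "label", "value")),
                as_trip(x$omega, c("i", "j", "label", "value")),
                as_trip(x$gamma, c("i", "label", "value")),
                as.character(unlist(x$par_lambda)),
                as.character(unlist(x$par_omega)),
                as.character(unlist(x$par_gamma)))
}
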