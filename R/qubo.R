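# QUBO encoding of the directed TSP over n^2 binary variables, and the
# exact QUBO <-> Ising transform.
#
# Variable indexing: x_{i,p} = 1 iff node i (0-based) occupies time slot
# p (0-based) of the cycle. Variable u (1-based R index) corresponds to
# i = (u-1) %/% n, p = (u-1) %% n, labelled "n{i}t{p}".
#
# Storage convention: Q is N x N with the total coefficient of each
# unordered pair {u, v} stored ONCE in the upper triangle (u < v);
# the energy is y = sum_u Q[u,u] x_u + sum_{u<v} Q[u,v] x_u x_v. With
# this single-count convention a valid permutation assignment has energy
# n*a + tour cost, and the nonzero strict-upper-triangle census equals
# the closed form 2 n^2 (n-1).

qubo_labels <- function(n) {
  i <- rep(seq_len(n) - 1L, each = n)
  p <- rep(seq_len(n) - 1L, times = n)
  sprintf("n%dt%d", i, p)
}

#' Encode a directed TSP instance as a QUBO model
#'
#' Builds the `N = n^2`-variable quadratic model whose ground states are
#' the valid tour assignments of minimum cost. Four coefficient classes
#' are accumulated into the upper triangle:
#' \itemize{
#'   \item diagonal `a` on every variable (assignment reward/bias);
#'   \item `b` on every pair of distinct nodes sharing a time slot
#'     (multi-location penalty: two cities at once);
#'   \item `c` on every pair of distinct time slots sharing a node
#'     (repetition penalty: a city visited twice);
#'   \item the directed edge weight `w(i, j)` on the pair
#'     `{(i, p), (j, (p+1) mod n)}` for every ordered edge and every
#'     slot `p` -- the modulo makes the encoding a cycle, not a path.
#' }
#'
#' @param tsp a `tsp_instance`.
#' @param a diagonal bias per variable (default 0: no reward needed when
#'   the penalties are sufficient).
#' @param b multi-location penalty (>= 0), default 13.
#' @param c repetition penalty (>= 0), default 13.
#' @return An object of class `qubo_model`: `n`, `N = n^2`, `Q`
#'   (upper-triangular coefficient matrix), `labels`, `params`.
#' @seealso [penalty_sufficient()] for the theoretical
#'   `n * max |w|` penalty preset.
#' @export
tsp_to_qubo <- function(tsp, a = 0, b = 13, c = 13) {
  stopifnot(inherits(tsp, "tsp_instance"))
  n <- tsp$n
  if (n < 2L) stop("n must be >= 2")
  if (b < 0 || c < 0) stop("penalties b and c must be nonnegative")
  N <- n * n
  Q <- matrix(0, N, N)
  vidx <- function(i, p) i * n + p + 1L  # i, p 0-based -> 1-based variable index
  diag(Q) <- a
  add <- function(u, v, coef) {
    lo <- min(u, v); hi <- max(u, v)
    Q[lo, hi] <<- Q[lo, hi] + coef
  }
  for (p in 0:(n - 1L)) {
    for (i in 0:(n - 2L)) for (j in (i + 1L):(n - 1L)) add(vidx(i, p), vidx(j, p), b)
  }
  for (i in 0:(n - 1L)) {
    for (p in 0:(n - 2L)) for (q in (p + 1L):(n - 1L)) add(vidx(i, p), vidx(i, q), c)
  }
  for (i in 0:(n - 1L)) {
    for (j in 0:(n - 1L)) {
      if (i == j) next
      w <- tsp$weights[i + 1L, j + 1L]
      for (p in 0:(n - 1L)) add(vidx(i, p), vidx(j, (p + 1L) %% n), w)
    }
  }
  labels <- qubo_labels(n)
  dimnames(Q) <- list(labels, labels)
  # `c` is an argument name here, so call base::c explicitly
  qubo <- list(n = n, N = N, Q = Q, labels = labels,
               params = base::c(a = a, b = b, c = c))
  class(qubo) <- "qubo_model"
  qubo
}

#' Construct a QUBO model from an explicit coefficient matrix
#'
#' Low-level constructor (the TSP route is [tsp_to_qubo()]). `Q` must be
#' upper-triangular: the total coefficient of each unordered pair stored
#' once, diagonal entries the linear terms.
#'
#' @param Q square numeric matrix with zero strict lower triangle.
#' @param n optional node count when the model encodes a tour
#'   assignment (`N = n^2`); defaults to `NA` for generic models.
#' @param labels optional variable names.
#' @return A `qubo_model`.
#' @export
qubo_model <- function(Q, n = NA_integer_, labels = NULL) {
  Q <- as.matrix(Q)
  N <- nrow(Q)
  stopifnot(ncol(Q) == N)
  if (any(Q[lower.tri(Q)] != 0)) {
    stop("Q must be upper-triangular (single-count convention)")
  }
  if (is.null(labels)) {
    labels <- if (!is.na(n) && n * n == N) qubo_labels(n) else paste0("x", seq_len(N) - 1L)
  }
  dimnames(Q) <- list(labels, labels)
  qubo <- list(n = as.integer(n), N = N, Q = Q, labels = labels,
               params = base::c(a = NA_real_, b = NA_real_, c = NA_real_))
  class(qubo) <- "qubo_model"
  qubo
}

#' Theoretically sufficient constraint penalty for a TSP instance
#'
#' The standard choice `n * max |w(i, j)|`: large enough that violating
#' one assignment constraint can never be compensated by collecting
#' edge rewards. Offered as an alternative to the empirical default
#' `b = c = 13` used for the four-read example.
#'
#' @param tsp a `tsp_instance`.
#' @return A single number usable as `b` and `c` in [tsp_to_qubo()].
#' @export
penalty_sufficient <- function(tsp) {
  tsp$n * max(abs(tsp$weights))
}

#' @export
print.qubo_model <- function(x, ...) {
  cat(sprintf("qubo_model: n = %d nodes, N = %d binary variables\n", x$n, x$N))
  cat(sprintf("params: a = %g, b = %g, c = %g; %d pairwise interactions\n",
              x$params["a"], x$params["b"], x$params["c"], interaction_count(x)))
  invisible(x)
}

#' Count pairwise interactions of a QUBO model
#'
#' Nonzero strict-upper-triangle entries. For the TSP encoding with
#' nonzero penalties and all-nonzero edge weights this equals the
#' closed form `2 n^2 (n - 1)`.
#'
#' @param qubo a `qubo_model`.
#' @return Integer count.
#' @export
interaction_count <- function(qubo) {
  U <- qubo$Q
  U[lower.tri(U, diag = TRUE)] <- 0
  sum(U != 0)
}

#' QUBO energy of one binary assignment
#'
#' `y = sum_u Q[u,u] x_u + sum_{u<v} Q[u,v] x_u x_v`.
#'
#' @param qubo a `qubo_model`.
#' @param x binary vector of length `qubo$N` (values 0/1).
#' @return Scalar energy.
#' @export
qubo_energy <- function(qubo, x) {
  x <- as.numeric(x)
  if (length(x) != qubo$N) stop(sprintf("x must have length N = %d", qubo$N))
  if (!all(x %in% c(0, 1))) stop("x must be binary (0/1)")
  drop(x %*% qubo$Q %*% x)  # x^2 = x for binary x, so diagonal terms are linear
}

# Vectorized energies for a matrix of binary states (rows).
qubo_energies <- function(qubo, X) {
  U <- qubo$Q
  d <- diag(U)
  diag(U) <- 0
  as.numeric(X %*% d + rowSums((X %*% U) * X))
}

#' Exact transform of a QUBO model to an Ising model
#'
#' Substitutes `x_u = (1 + s_u) / 2` exactly, so that for every state
#' `ising_energy(s, include_offset = TRUE) == qubo_energy(x(s))`:
#' `h_u = Q[u,u]/2 + (sum of pair coefficients touching u)/4`,
#' `J[u,v] = Q[u,v]/4`, and
#' `offset = sum_u Q[u,u]/2 + sum_{u<v} Q[u,v]/4`.
#'
#' @param qubo a `qubo_model`.
#' @return An object of class `ising_model`: `N`, `h` (linear biases),
#'   `J` (upper-triangular coupling matrix), `offset`, `labels`.
#' @export
qubo_to_ising <- function(qubo) {
  U <- qubo$Q
  d <- diag(U)
  diag(U) <- 0
  U[lower.tri(U)] <- 0
  h <- d / 2 + (rowSums(U) + colSums(U)) / 4
  J <- U / 4
  offset <- sum(d) / 2 + sum(U) / 4
  ising <- list(N = qubo$N, h = as.numeric(h), J = J, offset = offset,
                labels = qubo$labels)
  class(ising) <- "ising_model"
  ising
}

#' Construct an Ising model directly
#'
#' @param h numeric vector of linear biases.
#' @param J upper-triangular coupling matrix (entries with row >= col
#'   must be zero); defaults to no couplings.
#' @param offset constant energy offset (default 0).
#' @param labels optional spin labels.
#' @return An `ising_model`.
#' @export
ising_model <- function(h, J = NULL, offset = 0, labels = NULL) {
  N <- length(h)
  if (is.null(J)) J <- matrix(0, N, N)
  J <- as.matrix(J)
  stopifnot(nrow(J) == N, ncol(J) == N)
  if (any(J[lower.tri(J, diag = TRUE)] != 0)) {
    stop("J must be strictly upper-triangular (single-count convention)")
  }
  if (is.null(labels)) labels <- paste0("s", seq_len(N) - 1L)
  ising <- list(N = N, h = as.numeric(h), J = J, offset = offset, labels = labels)
  class(ising) <- "ising_model"
  ising
}

#' @export
print.ising_model <- function(x, ...) {
  cat(sprintf("ising_model: N = %d spins, %d couplings, offset = %g\n",
              x$N, sum(x$J != 0), x$offset))
  invisible(x)
}

#' Ising energy of one spin configuration
#'
#' `E = sum_u h_u s_u + sum_{u<v} J[u,v] s_u s_v (+ offset)`.
#'
#' @param ising an `ising_model`.
#' @param s spin vector over \{-1, +1\} of length `ising$N`.
#' @param include_offset add the constant offset (default `TRUE`, which
#'   makes the energy identical to the source QUBO's).
#' @return Scalar energy.
#' @export
ising_energy <- function(ising, s, include_offset = TRUE) {
  s <- as.numeric(s)
  if (length(s) != ising$N) stop(sprintf("s must have length N = %d", ising$N))
  if (!all(s %in% c(-1, 1))) stop("s must be a spin vector over {-1, +1}")
  e <- sum(ising$h * s) + drop(s %*% ising$J %*% s)
  if (include_offset) e <- e + ising$offset
  e
}

# Vectorized energies for a matrix of spin states (rows).
ising_energies <- function(ising, S, include_offset = TRUE) {
  e <- as.numeric(S %*% ising$h + rowSums((S %*% ising$J) * S))
  if (include_offset) e <- e + ising$offset
  e
}

#' Symmetrized view of the coefficient matrix
#'
#' Each unordered pair's coefficient split half-and-half across the two
#' off-diagonal cells, for export to tools expecting a symmetric Q. The
#' quadratic form `x^T Q_sym x` equals the single-count energy.
#'
#' @param qubo a `qubo_model`.
#' @return A symmetric `N x N` matrix.
#' @export
symmetrize <- function(qubo) {
  U <- qubo$Q
  d <- diag(U)
  diag(U) <- 0
  S <- (U + t(U)) / 2
  diag(S) <- d
  S
}

#' Export a model as plain-text COO triples
#'
#' One line per nonzero coefficient, `"u v coefficient"` with 0-based
#' variable indices; diagonal entries (`u == v`) are the linear terms.
#' A JSON header line (prefixed `#`) records `n`, labels and parameters
#' (QUBO) or the offset (Ising, with `h` written as diagonal triples).
#'
#' @param model a `qubo_model` or `ising_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coo <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(model, "qubo_model")) {
    hdr <- list(type = "qubo", n = model$n, labels = model$labels,
                params = as.list(model$params))
    M <- model$Q
  } else if (inherits(model, "ising_model")) {
    hdr <- list(type = "ising", labels = model$labels, offset = model$offset)
    M <- model$J
    diag(M) <- model$h
  } else stop("model must be a qubo_model or ising_model")
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
  nz <- which(M != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] <= nz[, 2], , drop = FALSE]
  writeLines(sprintf("%d %d %.17g", nz[, 1] - 1L, nz[, 2] - 1L, M[nz]), con)
  invisible(path)
}
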