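# Cost Hamiltonian as a weighted sum of Pauli products (words over
# {I, X, Y, Z}; only I/Z arise here, so the operator is diagonal in the
# computational basis).
#
# Bit/eigenvalue convention: qubit q (0-based) is character position
# q + 1 of the word and of basis bitstrings; bit 0 maps to Z eigenvalue
# +1, bit 1 to -1 (x_q = (1 - z_q) / 2). Basis state index i in
# 0..2^N-1 has bit q with weight 2^(N-1-q), i.e. bitstrings read
# left-to-right as q0 q1 ... q_{N-1}.

#' Weighted sum of Pauli products
#'
#' @param coeff numeric coefficients.
#' @param word character vector of length-`N` words over I/X/Y/Z.
#' @param N qubit count.
#' @param merge merge duplicate words by summing coefficients and drop
#'   exact zeros (default `TRUE`).
#' @return An object of class `pauli_hamiltonian` with a `terms`
#'   data.frame (`coeff`, `word`) and `N`.
#' @export
pauli_hamiltonian <- function(coeff, word, N, merge = TRUE) {
  stopifnot(length(coeff) == length(word))
  if (any(nchar(word) != N)) stop(sprintf("every word must have length N = %d", N))
  if (any(grepl("[^IXYZ]", word))) stop("words must be over the alphabet I/X/Y/Z")
  if (merge && length(word)) {
    agg <- tapply(coeff, word, sum)
    keep <- names(agg)[abs(agg) > 0]
    # preserve first-appearance order of surviving words
    keep <- word[!duplicated(word)][word[!duplicated(word)] %in% keep]
    coeff <- as.numeric(agg[keep]); word <- keep
  }
  ham <- list(terms = data.frame(coeff = coeff, word = word,
                                 stringsAsFactors = FALSE),
              N = as.integer(N))
  class(ham) <- "pauli_hamiltonian"
  ham
}

#' @export
print.pauli_hamiltonian <- function(x, n = 8L, ...) {
  cat(sprintf("pauli_hamiltonian: %d qubits, %d terms\n", x$N, nrow(x$terms)))
  m <- min(n, nrow(x$terms))
  for (k in seq_len(m)) cat(sprintf("  %+g * %s\n", x$terms$coeff[k], x$terms$word[k]))
  if (nrow(x$terms) > m) cat(sprintf("  ... %d more\n", nrow(x$terms) - m))
  invisible(x)
}

# Z-word over positions (0-based qubit indices)
z_word <- function(qubits, N) {
  w <- rep("I", N)
  w[qubits + 1L] <- "Z"
  paste(w, collapse = "")
}

#' Build the QAOA cost Hamiltonian for a directed TSP instance
#'
#' Four term classes over `N = n^2` qubits (qubit `i*n + p` encodes
#' "node i at slot p"):
#' \itemize{
#'   \item assignment pressure: `+w Z_q` for every qubit;
#'   \item co-location (two nodes, one slot): for each slot `r` and node
#'     pair `i > j`, `-w/2 Z_{in+r} - w/2 Z_{jn+r} + w/2 Z_{in+r} Z_{jn+r}`;
#'   \item repetition (one node, two slots): for each node `i` and slot
#'     pair `r > s`, `-w/2 Z_{in+r} - w/2 Z_{in+s} + w/2 Z_{in+r} Z_{in+s}`;
#'   \item path cost: for each ordered edge `(i, j)` and slot `r` with
#'     `s = (r+1) mod n`,
#'     `-d/4 Z_{in+r} - d/4 Z_{jn+s} + d/4 Z_{in+r} Z_{jn+s}` where `d`
#'     is the directed TSP edge weight (a negated overlap, used verbatim).
#' }
#' Duplicate words are merged by summing coefficients; only nonzero
#' terms are stored (the full Pauli basis over 16 qubits would have
#' `4^16 = 4294967296` terms).
#'
#' @param tsp a `tsp_instance`.
#' @param w assignment-pressure weight (default `1e5`).
#' @param penalty co-location/repetition weight; the default reuses `w`.
#' @return A diagonal [pauli_hamiltonian()] over `n^2` qubits.
#' @export
build_cost_hamiltonian <- function(tsp, w = 1e5, penalty = w) {
  stopifnot(inherits(tsp, "tsp_instance"))
  n <- tsp$n
  N <- n * n
  coeff <- numeric(0); word <- character(0)
  push <- function(co, qs) {
    coeff[length(coeff) + 1L] <<- co
    word[length(word) + 1L] <<- z_word(qs, N)
  }
  # HC1: assignment pressure on every qubit
  for (q in 0:(N - 1L)) push(w, q)
  # HC2: co-location
  for (r in 0:(n - 1L)) for (i in 1:(n - 1L)) for (j in 0:(i - 1L)) {
    a <- i * n + r; b <- j * n + r
    push(-penalty / 2, a); push(-penalty / 2, b); push(penalty / 2, c(a, b))
  }
  # HC3: repetition
  for (i in 0:(n - 1L)) for (r in 1:(n - 1L)) for (s in 0:(r - 1L)) {
    a <- i * n + r; b <- i * n + s
    push(-penalty / 2, a); push(-penalty / 2, b); push(penalty / 2, c(a, b))
  }
  # HC4: path cost on consecutive slots (cyclic)
  for (i in 0:(n - 1L)) for (j in 0:(n - 1L)) {
    if (i == j) next
    d <- tsp$weights[i + 1L, j + 1L]
    for (r in 0:(n - 1L)) {
      s <- (r + 1L) %% n
      a <- i * n + r; b <- j * n + s
      push(-d / 4, a); push(-d / 4, b); push(d / 4, c(a, b))
    }
  }
  pauli_hamiltonian(coeff, word, N)
}

#' Diagonal of a Pauli Hamiltonian over all basis states
#'
#' For a Hamiltonian containing only I/Z words, returns the vector of
#' `2^N` eigenvalues: entry for basis state `x` is
#' `sum_terms coeff * prod_{q : word[q] = Z} z_q` with `z_q = +1` for
#' bit 0 and `-1` for bit 1.
#'
#' @param ham a diagonal [pauli_hamiltonian()].
#' @return Numeric vector of length `2^N`, indexed by basis state
#'   (state 1 is `|00...0>`).
#' @export
diagonal_energies <- function(ham) {
  if (any(grepl("[XY]", ham$terms$word))) {
    stop("diagonal_energies requires a diagonal Hamiltonian (words over I/Z only)")
  }
  N <- ham$N
  nstates <- 2^N
  idx <- seq_len(nstates) - 1
  zq <- function(q) 1 - 2 * bitwAnd(idx %/% (2^(N - 1 - q)), 1L)  # q 0-based
  E <- numeric(nstates)
  for (k in seq_len(nrow(ham$terms))) {
    qs <- which(strsplit(ham$terms$word[k], "", fixed = TRUE)[[1]] == "Z") - 1L
    v <- rep(ham$terms$coeff[k], nstates)
    for (q in qs) v <- v * zq(q)
    E <- E + v
  }
  E
}

#' Export a Pauli Hamiltonian as plain text
#'
#' One term per line, `"coefficient word"`.
#'
#' @param ham a [pauli_hamiltonian()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pauli <- function(ham, path) {
  writeLines(sprintf("%.17g %s", ham$terms$coeff, ham$terms$word), path)
  invisible(path)
}
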