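# Shared fixtures and independent oracles. The four-read example:
# length-10 windows of the circular genome ATGGCGTGCA at offsets
# 0, 3, 6, 9.

example_genome <- "ATGGCGTGCA"

example_reads <- c("ATGGCGTGCA", "GCGTGCAATG", "TGCAATGGCG", "AATGGCGTGC")

example_readset <- function() read_set(example_reads)

example_tsp <- function() reads_to_tsp(example_readset())

# the 12 published directed edge weights, (i, j) 0-based
example_weights <- list(
  c(0, 1, -7), c(1, 2, -7), c(2, 3, -7), c(3, 0, -9),
  c(1, 0, -3), c(2, 1, -3), c(3, 2, -3), c(0, 3, -1),
  c(0, 2, -4), c(1, 3, -4), c(2, 0, -6), c(3, 1, -6)
)

# the four degenerate ground-state assignments (rotations of tour
# 0 -> 1 -> 2 -> 3), as bitstrings over [n0t0 | n0t1 | ... | n3t3]
type_a_bitstrings <- c(
  "1000010000100001",
  "0100001000011000",
  "0010000110000100",
  "0001100001000010"
)

# --- independent oracles -----------------------------------------------------

# exhaustive-k suffix-prefix overlap
overlap_oracle <- function(a, b) {
  best <- 0L
  for (k in seq_len(min(nchar(a), nchar(b)) - 1L)) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) best <- k
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# full-matrix quadratic form with half-weights on each side: an
# independent evaluation route for QUBO energies
qubo_energy_oracle <- function(qubo, x) {
  S <- symmetrize(qubo)
  drop(x %*% S %*% x)
}

# independent start-fixed tour scan: filters all n^n index tuples down
# to permutations starting at 1 (differs from the package's recursive
# permutation generator)
optimal_tours_oracle <- function(tsp) {
  n <- tsp$n
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perm <- grid[apply(grid, 1, function(r) r[1] == 1L && !anyDuplicated(r)), , drop = FALSE]
  costs <- apply(perm, 1, function(t) {
    nxt <- c(t[-1], t[1])
    sum(tsp$weights[cbind(t, nxt)])
  })
  lapply(which(costs <= min(costs) + 1e-9), function(k) unname(perm[k, ]))
}

# per-state, term-by-term diagonal evaluation of a Pauli Hamiltonian
diagonal_oracle <- function(ham) {
  N <- ham$N
  vapply(0:(2^N - 1), function(i) {
    bits <- bitwAnd(i %/% 2^(N - 1 - (0:(N - 1))), 1L)
    z <- 1 - 2 * bits
    tot <- 0
    for (k in seq_len(nrow(ham$terms))) {
      qs <- which(strsplit(ham$terms$word[k], "")[[1]] == "Z")
      tot <- tot + ham$terms$coeff[k] * prod(z[qs])
    }
    tot
  }, numeric(1))
}

# dense Kronecker-product circuit simulation for small N
kron_oracle <- function(circuit, gammas, betas) {
  N <- circuit$N
  I2 <- diag(2)
  X <- matrix(c(0, 1, 1, 0), 2)
  embed1 <- function(U, q) {
    M <- 1
    for (k in 0:(N - 1)) M <- kronecker(M, if (k == q) U else I2)
    M
  }
  embed_cnot <- function(ctrl, targ) {
    P0 <- matrix(c(1, 0, 0, 0), 2)
    P1 <- matrix(c(0, 0, 0, 1), 2)
    M0 <- 1; M1 <- 1
    for (k in 0:(N - 1)) {
      M0 <- kronecker(M0, if (k == ctrl) P0 else I2)
      M1 <- kronecker(M1, if (k == ctrl) P1 else if (k == targ) X else I2)
    }
    M0 + M1
  }
  gmat <- function(g) {
    if (g$name == "CNOT") return(embed_cnot(g$qubits[1], g$qubits[2]))
    theta <- if (g$name == "H") NA_real_ else quboasm:::resolve_angle(g, gammas, betas)
    embed1(quboasm:::gate_matrix(g$name, theta), g$qubits[1])
  }
  state <- complex(2^N); state[1] <- 1
  for (g in circuit$prologue) state <- gmat(g) %*% state
  for (blk in circuit$blocks) {
    for (g in blk$cost) state <- gmat(g) %*% state
    for (g in blk$mixer) state <- gmat(g) %*% state
  }
  as.vector(state)
}

# bitstring helpers
bits_of <- function(s) as.integer(strsplit(s, "")[[1]])

config_strings <- function(ss) {
  X <- ss$configurations
  if (ss$convention == "spin") X <- (X + 1) / 2
  apply(X, 1, paste, collapse = "")
}
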