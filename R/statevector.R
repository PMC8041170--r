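# Dense statevector simulation of the QAOA ansatz.
#
# Angle conventions: RZ(theta) = exp(-i theta Z / 2) = diag(e^{-i t/2},
# e^{+i t/2}); RX(theta) = exp(-i theta X / 2). A cost term coeff * Z...
# is realized with theta = 2 * coeff * gamma, so one cost block applies
# exp(-i gamma H_C) exactly (no global-phase discrepancy for traceless
# words), and the mixer RX(2 beta) applies exp(-i beta X_q) per qubit.

#' Parameterized QAOA circuit
#'
#' A prologue (reference state preparation) followed by `steps` blocks,
#' each a cost layer (angles proportional to that step's gamma) then a
#' mixer layer (angles proportional to that step's beta). Gates carry an
#' angle *rule* `(slot, scale)`: the concrete angle at simulation time is
#' `scale * gamma[slot]` or `scale * beta[slot]` (or a fixed value).
#'
#' @param N qubit count.
#' @param prologue,blocks gate lists; each gate is
#'   `list(name, qubits, slot, scale, angle)` with `name` one of
#'   H/RZ/RX/CNOT, `qubits` 0-based, `slot` one of `"gamma"`, `"beta"`,
#'   `NA` (fixed), plus the step index.
#' @return An object of class `param_circuit`.
#' @keywords internal
param_circuit <- function(N, prologue, blocks) {
  pc <- list(N = as.integer(N), prologue = prologue, blocks = blocks)
  class(pc) <- "param_circuit"
  pc
}

gate <- function(name, qubits, slot = NA_character_, step = NA_integer_,
                 scale = NA_real_, angle = NA_real_) {
  list(name = name, qubits = as.integer(qubits), slot = slot,
       step = as.integer(step), scale = scale, angle = angle)
}

#' Compile the QAOA alternating ansatz from a diagonal cost Hamiltonian
#'
#' Prologue: Hadamard on every qubit (equal superposition reference
#' state). Per step: for every single-Z term on qubit `q`, an
#' `RZ(2 * coeff * gamma)` on `q`; for every ZZ term on `(a, b)`, a
#' `CNOT(a -> b)`, `RZ(2 * coeff * gamma)` on `b`, `CNOT(a -> b)`
#' sandwich; then the mixer, `RX(2 * beta)` on every qubit. All-identity
#' words contribute only a global phase and compile to no gate.
#'
#' @param ham a diagonal [pauli_hamiltonian()].
#' @param steps QAOA depth `p` (>= 1).
#' @return A `param_circuit` with `steps` blocks.
#' @export
build_ansatz <- function(ham, steps = 1L) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  if (any(grepl("[XY]", ham$terms$word))) stop("build_ansatz expects a diagonal (I/Z) Hamiltonian")
  N <- ham$N
  prologue <- lapply(0:(N - 1L), function(q) gate("H", q))
  zpos <- lapply(strsplit(ham$terms$word, "", fixed = TRUE),
                 function(chs) which(chs == "Z") - 1L)
  blocks <- lapply(seq_len(steps), function(st) {
    cost <- list()
    for (k in seq_along(zpos)) {
      qs <- zpos[[k]]
      co <- ham$terms$coeff[k]
      if (length(qs) == 0L) next
      if (length(qs) == 1L) {
        cost[[length(cost) + 1L]] <- gate("RZ", qs, "gamma", st, 2 * co)
      } else if (length(qs) == 2L) {
        cost[[length(cost) + 1L]] <- gate("CNOT", qs)
        cost[[length(cost) + 1L]] <- gate("RZ", qs[2], "gamma", st, 2 * co)
        cost[[length(cost) + 1L]] <- gate("CNOT", qs)
      } else {
        stop("only single-Z and ZZ words are supported by the ansatz compiler")
      }
    }
    mixer <- lapply(0:(N - 1L), function(q) gate("RX", q, "beta", st, 2))
    list(cost = cost, mixer = mixer)
  })
  param_circuit(N, prologue, blocks)
}

#' @export
print.param_circuit <- function(x, ...) {
  ng <- length(x$prologue) + sum(vapply(x$blocks, function(b) length(b$cost) + length(b$mixer), numeric(1)))
  cat(sprintf("param_circuit: %d qubits, %d steps, %d gates\n", x$N, length(x$blocks), ng))
  invisible(x)
}

# --- gate application (vectorized over the 2^N amplitude vector) ------------

# qubit q (0-based) has index weight 2^(N-1-q)
qubit_mask <- function(q, N) 2^(N - 1 - q)

apply_1q <- function(state, q, U, N) {
  m <- qubit_mask(q, N)
  idx <- seq_len(2^N) - 1
  p0 <- which(bitwAnd(idx, m) == 0)   # 1-based positions with bit q = 0
  p1 <- p0 + m
  a0 <- state[p0]; a1 <- state[p1]
  state[p0] <- U[1, 1] * a0 + U[1, 2] * a1
  state[p1] <- U[2, 1] * a0 + U[2, 2] * a1
  state
}

apply_cnot <- function(state, ctrl, targ, N) {
  mc <- qubit_mask(ctrl, N); mt <- qubit_mask(targ, N)
  idx <- seq_len(2^N) - 1
  sel <- which(bitwAnd(idx, mc) != 0 & bitwAnd(idx, mt) == 0)
  tmp <- state[sel]
  state[sel] <- state[sel + mt]
  state[sel + mt] <- tmp
  state
}

gate_matrix <- function(name, theta = NA_real_) {
  switch(name,
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    RZ = diag(c(exp(-1i * theta / 2), exp(1i * theta / 2))),
    RX = matrix(c(cos(theta / 2), -1i * sin(theta / 2),
                  -1i * sin(theta / 2), cos(theta / 2)), 2, 2),
    stop(sprintf("unknown gate '%s'", name))
  )
}

resolve_angle <- function(g, gammas, betas) {
  if (!is.na(g$angle)) return(g$angle)
  param <- switch(g$slot,
                  gamma = gammas[g$step],
                  beta = betas[g$step],
                  stop("gate has no angle rule"))
  g$scale * param
}

apply_gate <- function(state, g, gammas, betas, N) {
  if (g$name == "CNOT") return(apply_cnot(state, g$qubits[1], g$qubits[2], N))
  theta <- if (g$name == "H") NA_real_ else resolve_angle(g, gammas, betas)
  apply_1q(state, g$qubits[1], gate_matrix(g$name, theta), N)
}

#' Simulate a parameterized circuit on a dense statevector
#'
#' Gate-by-gate simulation starting from `|0...0>`. Guarded at
#' `N <= 20` (dense complex vector of `2^N` amplitudes).
#'
#' @param circuit a `param_circuit` from [build_ansatz()].
#' @param gammas,betas numeric vectors of per-step angles (lengths equal
#'   to the number of blocks).
#' @return Complex amplitude vector of length `2^N` (norm 1 to 1e-9).
#' @export
simulate_statevector <- function(circuit, gammas = numeric(0), betas = numeric(0)) {
  N <- circuit$N
  if (N > 20L) stop("statevector simulation is guarded at N <= 20 qubits")
  steps <- length(circuit$blocks)
  if (length(gammas) != steps || length(betas) != steps) {
    stop(sprintf("expected %d gamma and %d beta angles", steps, steps))
  }
  state <- complex(2^N)
  state[1] <- 1 + 0i
  for (g in circuit$prologue) state <- apply_gate(state, g, gammas, betas, N)
  for (blk in circuit$blocks) {
    for (g in blk$cost) state <- apply_gate(state, g, gammas, betas, N)
    for (g in blk$mixer) state <- apply_gate(state, g, gammas, betas, N)
  }
  state
}

# Per-qubit index tables for the mixer layer: positions (1-based) of
# the amplitudes with bit q = 0, reusable across objective evaluations.
qubit_pairs <- function(N) {
  idx <- seq_len(2^N) - 1
  masks <- 2^(N - 1 - (0:(N - 1L)))
  list(masks = masks,
       p0 = lapply(masks, function(m) which(bitwAnd(idx, m) == 0)))
}

# Fast QAOA state: the cost layer of a diagonal Hamiltonian is the
# diagonal phase exp(-i gamma E_x); the mixer is RX(2 beta) per qubit.
# Identical to simulate_statevector(build_ansatz(ham, p), ...) up to a
# global phase from all-identity words (absent in the TSP Hamiltonian).
qaoa_state <- function(diagE, N, gammas, betas, pairs = qubit_pairs(N)) {
  nstates <- 2^N
  state <- rep(complex(real = 2^(-N / 2)), nstates)  # H^⊗N |0>
  masks <- pairs$masks
  p0 <- pairs$p0
  for (st in seq_along(gammas)) {
    state <- state * exp(-1i * gammas[st] * diagE)
    cb <- cos(betas[st]); sb <- sin(betas[st])
    for (q in seq_len(N)) {
      i0 <- p0[[q]]; i1 <- i0 + masks[q]
      a0 <- state[i0]; a1 <- state[i1]
      state[i0] <- cb * a0 - 1i * sb * a1
      state[i1] <- -1i * sb * a0 + cb * a1
    }
  }
  state
}

#' Expectation value of a diagonal Hamiltonian in a state
#'
#' `sum_x |amp_x|^2 * E_x` where `E` is [diagonal_energies()] of the
#' Hamiltonian.
#'
#' @param state complex amplitude vector (norm within 1e-6 of 1).
#' @param ham a diagonal [pauli_hamiltonian()], or a precomputed numeric
#'   vector of diagonal energies of matching length.
#' @return Scalar expectation.
#' @export
expectation <- function(state, ham) {
  p <- Re(state * Conj(state))
  if (abs(sum(p) - 1) > 1e-6) stop("state is not normalized (norm deviation > 1e-6)")
  E <- if (is.numeric(ham)) ham else diagonal_energies(ham)
  if (length(E) != length(state)) stop("state and Hamiltonian dimensions differ")
  sum(p * E)
}

#' Measurement sampling from a statevector
#'
#' Multinomial draw of `shots` basis-state measurements from the
#' squared-amplitude distribution. `shots = 0` bypasses sampling and
#' returns the exact probabilities of every basis state with nonzero
#' probability (the simulator's internal state is accessed directly).
#'
#' @param state complex amplitude vector of length `2^N`.
#' @param shots number of measurements (>= 0).
#' @param seed integer RNG seed for reproducible draws.
#' @return Named numeric vector: counts per observed bitstring
#'   (`shots > 0`) or exact probabilities (`shots = 0`); names are
#'   bitstrings reading qubit 0 leftmost.
#' @export
sample_counts <- function(state, shots, seed = NULL) {
  N <- round(log2(length(state)))
  p <- Re(state * Conj(state))
  keys <- index_bitstrings(which(p > 0) - 1L, N)
  if (shots == 0) {
    out <- p[p > 0]
    names(out) <- keys
    return(out)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  draws <- stats::rmultinom(1, size = shots, prob = p[p > 0])[, 1]
  out <- draws[draws > 0]
  names(out) <- keys[draws > 0]
  out
}

# bitstrings (qubit 0 leftmost) for 0-based basis indices
index_bitstrings <- function(idx, N) {
  vapply(idx, function(i) {
    paste(bitwAnd(i %/% 2^(N - 1 - (0:(N - 1L))), 1L), collapse = "")
  }, character(1))
}
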