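test_that("the cost Hamiltonian has the expected term census for n = 4", {
  ham <- build_cost_hamiltonian(example_tsp())
  nz <- vapply(strsplit(ham$terms$word, ""), function(ch) sum(ch == "Z"), numeric(1))
  expect_equal(sum(nz == 1), 16)  # one merged single-Z term per qubit
  expect_equal(sum(nz == 2), 96)  # matches the QUBO pair census 24+24+48
  expect_true(all(nz %in% 1:2))
  expect_lt(nrow(ham$terms), 300)  # sparse vs the 4^16 all-Pauli bound
  expect_true(all(abs(ham$terms$coeff) > 0))
})

test_that("pauli_hamiltonian merges duplicate words and validates input", {
  ham <- pauli_hamiltonian(c(1, 2, -3), c("ZI", "ZI", "IZ"), 2)
  expect_equal(nrow(ham$terms), 2)
  expect_equal(ham$terms$coeff[ham$terms$word == "ZI"], 3)
  cancel <- pauli_hamiltonian(c(1, -1), c("ZZ", "ZZ"), 2)
  expect_equal(nrow(cancel$terms), 0)
  expect_error(pauli_hamiltonian(1, "ZQ", 2), "alphabet")
  expect_error(pauli_hamiltonian(1, "Z", 2), "length")
})

test_that("diagonal_energies matches the term-by-term oracle and trivial cases", {
  const <- pauli_hamiltonian(2.5, "III", 3)
  expect_equal(diagonal_energies(const), rep(2.5, 8))

  set.seed(37)
  words <- c("ZIIIII", "IZIIII", "ZZIIII", "IIZIZI", "IIIIIZ", "ZIIIIZ")
  ham <- pauli_hamiltonian(round(stats::runif(6, -5, 5), 2), words, 6)
  expect_equal(diagonal_energies(ham), diagonal_oracle(ham), tolerance = 1e-12)
  expect_error(diagonal_energies(pauli_hamiltonian(1, "XI", 2)), "diagonal")
})

test_that("the example diagonal argmin is the four published bitstrings", {
  E <- diagonal_energies(build_cost_hamiltonian(example_tsp()))
  am <- which(E <= min(E) + 1e-6) - 1L
  expect_setequal(quboasm:::index_bitstrings(am, 16), type_a_bitstrings)
})

test_that("diagonal energies rank tours identically to tour_cost", {
  set.seed(41)
  for (n in 2:3) {
    tsp <- tsp_instance(matrix(-sample(0:9, n * n, replace = TRUE), n, n))
    E <- diagonal_energies(build_cost_hamiltonian(tsp))
    tours <- enumerate_unique_tours(n)
    costs <- vapply(tours, function(t) tour_cost(tsp, t), numeric(1))
    idx <- vapply(tours, function(t) {
      bits <- encode_assignment(t)
      sum(bits * 2^(n * n - seq_len(n * n))) + 1
    }, numeric(1))
    expect_equal(rank(E[idx], ties.method = "average"),
                 rank(costs, ties.method = "average"))
  }
})

test_that("QUBO and diagonal-Hamiltonian argmins agree on random 3-node instances", {
  set.seed(43)
  for (rep in 1:20) {
    tsp <- tsp_instance(matrix(-sample(0:9, 9, replace = TRUE), 3, 3))
    qubo <- tsp_to_qubo(tsp, a = 0, b = penalty_sufficient(tsp) + 1,
                        c = penalty_sufficient(tsp) + 1)
    ss <- solve_exact(qubo)
    E <- diagonal_energies(build_cost_hamiltonian(tsp))
    am <- quboasm:::index_bitstrings(which(E <= min(E) + 1e-6) - 1L, 9)
    expect_setequal(am, config_strings(ss))
  }
})

test_that("build_ansatz lays out prologue, cost and mixer layers", {
  h1 <- pauli_hamiltonian(0.7, "Z", 1)
  c1 <- build_ansatz(h1, 1)
  gates <- c(vapply(c1$prologue, function(g) g$name, character(1)),
             vapply(c1$blocks[[1]]$cost, function(g) g$name, character(1)),
             vapply(c1$blocks[[1]]$mixer, function(g) g$name, character(1)))
  expect_equal(gates, c("H", "RZ", "RX"))
  expect_equal(c1$blocks[[1]]$cost[[1]]$scale, 2 * 0.7)

  circ <- build_ansatz(build_cost_hamiltonian(example_tsp()), 1)
  expect_length(circ$blocks, 1)
  expect_length(circ$blocks[[1]]$mixer, 16)
  # each ZZ term compiles to one CNOT-RZ-CNOT sandwich
  names1 <- vapply(circ$blocks[[1]]$cost, function(g) g$name, character(1))
  expect_equal(sum(names1 == "CNOT"), 2 * 96)
  expect_equal(sum(names1 == "RZ"), 16 + 96)

  two <- build_ansatz(pauli_hamiltonian(1, "ZZ", 2), 2)
  expect_length(two$blocks, 2)
  expect_equal(two$blocks[[2]]$cost[[2]]$step, 2L)
  expect_equal(two$blocks[[2]]$cost[[2]]$slot, "gamma")
  expect_error(build_ansatz(h1, 0), "steps")
})

test_that("simulate_statevector reproduces trivial states", {
  empty <- quboasm:::param_circuit(3, list(), list())
  s <- simulate_statevector(empty)
  expect_equal(s[1], 1 + 0i)
  expect_equal(sum(abs(s)), 1)

  prologue <- quboasm:::param_circuit(
    4, lapply(0:3, function(q) quboasm:::gate("H", q)), list())
  s <- simulate_statevector(prologue)
  expect_equal(s, rep(complex(real = 0.25), 16), tolerance = 1e-12)
})

test_that("the simulator agrees with a dense Kronecker oracle on small circuits", {
  set.seed(47)
  for (trial in 1:100) {
    N <- sample(2:4, 1)
    words <- replicate(3, {
      qs <- sort(sample(0:(N - 1), sample(1:2, 1)))
      quboasm:::z_word(qs, N)
    })
    ham <- pauli_hamiltonian(round(stats::runif(3, -2, 2), 2), words, N)
    if (nrow(ham$terms) == 0) next
    steps <- sample(1:2, 1)
    circ <- build_ansatz(ham, steps)
    g <- stats::runif(steps, 0, 2 * pi)
    b <- stats::runif(steps, 0, 2 * pi)
    got <- simulate_statevector(circ, g, b)
    want <- kron_oracle(circ, g, b)
    expect_lt(max(abs(got - want)), 1e-9)
    expect_lt(abs(sum(abs(got)^2) - 1), 1e-9)
  }
})

test_that("the fast QAOA path equals the gate-compiled ansatz on the example", {
  ham <- build_cost_hamiltonian(example_tsp())
  circ <- build_ansatz(ham, 1)
  set.seed(53)
  g <- stats::runif(1, 0, 2 * pi); b <- stats::runif(1, 0, 2 * pi)
  gate_state <- simulate_statevector(circ, g, b)
  fast_state <- quboasm:::qaoa_state(diagonal_energies(ham), 16, g, b)
  expect_lt(max(abs(gate_state - fast_state)), 1e-9)
})

test_that("expectation handles basis states, superpositions and the zero-angle limit", {
  ham <- pauli_hamiltonian(c(1, -2), c("ZI", "ZZ"), 2)
  E <- diagonal_energies(ham)
  basis <- complex(4); basis[3] <- 1  # |10>
  expect_equal(expectation(basis, ham), E[3])
  eq <- rep(complex(real = 0.5), 4)
  expect_equal(expectation(eq, ham), mean(E))
  expect_error(expectation(c(1 + 0i, 1 + 0i), pauli_hamiltonian(1, "Z", 1)),
               "not normalized")

  hamx <- build_cost_hamiltonian(example_tsp())
  Ex <- diagonal_energies(hamx)
  zero <- quboasm:::qaoa_state(Ex, 16, 0, 0)
  expect_equal(expectation(zero, Ex), mean(Ex), tolerance = 1e-6)
  expect_equal(unname(range(abs(zero)^2)), rep(1 / 65536, 2), tolerance = 1e-12)
})

test_that("sample_counts draws reproducibly and bypasses at shots = 0", {
  basis <- complex(4); basis[2] <- 1
  counts <- sample_counts(basis, 100, seed = 1)
  expect_equal(unname(counts), 100)
  expect_equal(names(counts), "01")

  eq <- rep(complex(real = 0.5), 4)
  counts <- sample_counts(eq, 10000, seed = 2)
  expect_true(all(abs(counts - 2500) < 5 * sqrt(10000 * 0.25 * 0.75)))
  expect_identical(counts, sample_counts(eq, 10000, seed = 2))

  probs <- sample_counts(eq, 0)
  expect_equal(unname(probs), rep(0.25, 4))
})

test_that("a one-qubit QAOA landscape reaches its closed-form optimum", {
  # cost -Z: optimum expectation -1 is attainable at depth 1
  diagE <- c(-1, 1)
  obj <- function(theta) {
    st <- quboasm:::qaoa_state(diagE, 1, theta[1], theta[2])
    sum(abs(st)^2 * diagE)
  }
  set.seed(59)
  best <- Inf
  for (r in 1:10) {
    fit <- stats::optim(stats::runif(2, 0, 2 * pi), obj, method = "Nelder-Mead")
    best <- min(best, fit$value)
  }
  expect_lte(best, -0.99)
})

test_that("run_qaoa improves on the zero-angle expectation and is seed-stable", {
  tsp <- tsp_instance(matrix(c(0, -3, -1, 0), 2, 2, byrow = TRUE))
  r1 <- run_qaoa(tsp, steps = 1, w = 10, restarts = 5, max_iter = 100, seed = 61)
  r2 <- run_qaoa(tsp, steps = 1, w = 10, restarts = 5, max_iter = 100, seed = 61)
  expect_equal(r1$expectation, r2$expectation)
  expect_equal(r1$gammas, r2$gammas)
  expect_true(all(diff(r1$trace) <= 1e-12))
  zero_angle <- mean(diagonal_energies(build_cost_hamiltonian(tsp, w = 10)))
  expect_lte(r1$expectation, zero_angle)
  expect_true(all(r1$probabilities >= 0 & r1$probabilities <= 1))
  expect_lte(sum(r1$probabilities), 1 + 1e-9)
  expect_error(run_qaoa(tsp, optimizer = "Adam"), "supported")
})
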