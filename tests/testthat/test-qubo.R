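test_that("the example QUBO has the published argmin set and tour-cost energies", {
  qubo <- tsp_to_qubo(example_tsp(), a = 0, b = 13, c = 13)
  expect_equal(qubo$N, 16)
  expect_equal(qubo$labels[1:5], c("n0t0", "n0t1", "n0t2", "n0t3", "n1t0"))

  # exhaustive argmin via the independent symmetric-matrix oracle
  X <- quboasm:::state_bits(0:65535, 16)
  S <- symmetrize(qubo)
  E <- rowSums((X %*% S) * X)
  minima <- which(E <= min(E) + 1e-9)
  got <- apply(X[minima, ], 1, paste, collapse = "")
  expect_setequal(got, type_a_bitstrings)
  expect_equal(min(E), -30)

  for (bs in type_a_bitstrings) {
    expect_equal(qubo_energy(qubo, bits_of(bs)), -30)
  }
})

test_that("a 2-node toy QUBO with zero weights has the penalty-free states as minima", {
  # with a = 0 there is no occupancy reward, so every assignment that
  # triggers no b/c penalty pair sits at the minimum energy 0: the empty
  # and singleton assignments plus the two permutation assignments
  # (computed by enumerating all 16 states)
  qubo <- tsp_to_qubo(tsp_instance(matrix(0, 2, 2)), a = 0, b = 1, c = 1)
  X <- quboasm:::state_bits(0:15, 4)
  E <- apply(X, 1, function(x) qubo_energy(qubo, x))
  minima <- apply(X[E <= min(E) + 1e-9, ], 1, paste, collapse = "")
  expect_setequal(minima, c("0000", "1000", "0100", "0010", "0001",
                            "1001", "0110"))
  expect_equal(min(E), 0)
  expect_true(all(c("1001", "0110") %in% minima))
  # a negative reward makes occupancy pay: only the permutations remain
  rewarded <- tsp_to_qubo(tsp_instance(matrix(0, 2, 2)), a = -1, b = 2, c = 2)
  Er <- apply(X, 1, function(x) qubo_energy(rewarded, x))
  expect_setequal(apply(X[Er <= min(Er) + 1e-9, ], 1, paste, collapse = ""),
                  c("1001", "0110"))
})

test_that("interaction_count matches the closed form and a direct scan", {
  tsp4 <- example_tsp()
  expect_equal(interaction_count(tsp_to_qubo(tsp4)), 96)  # 2 * 16 * 3

  set.seed(5)
  for (n in 3:4) {
    w <- matrix(-sample(1:9, n * n, replace = TRUE), n, n)
    qubo <- tsp_to_qubo(tsp_instance(w), a = 0, b = 7, c = 5)
    expect_equal(interaction_count(qubo), 2 * n^2 * (n - 1))
    U <- qubo$Q; U[lower.tri(U, diag = TRUE)] <- 0
    expect_equal(interaction_count(qubo), sum(U != 0))
  }
  # n = 2 is the collision case: the two directions of each edge land on
  # the same variable pair {(i,p), (j,p+1 mod 2)} and are summed, so the
  # distinct-pair census is 6, below the no-collision closed form 8
  w2 <- matrix(c(0, -2, -3, 0), 2, 2, byrow = TRUE)
  qubo2 <- tsp_to_qubo(tsp_instance(w2), a = 0, b = 7, c = 5)
  expect_equal(interaction_count(qubo2), 6)
  expect_equal(qubo2$Q[1, 4], -5)  # w(0,1) + w(1,0) accumulated
  zero <- tsp_to_qubo(tsp_instance(matrix(0, 2, 2)), a = 0, b = 0, c = 0)
  expect_equal(interaction_count(zero), 0)
})

test_that("qubo_energy matches the full-matrix oracle on random states", {
  qubo <- tsp_to_qubo(example_tsp())
  expect_equal(qubo_energy(qubo, rep(0, 16)), 0)
  set.seed(13)
  for (i in 1:50) {
    x <- sample(0:1, 16, replace = TRUE)
    expect_equal(qubo_energy(qubo, x), qubo_energy_oracle(qubo, x))
  }
  expect_error(qubo_energy(qubo, rep(0, 15)), "length")
  expect_error(qubo_energy(qubo, c(rep(0, 15), 2)), "binary")
})

test_that("qubo_to_ising is the exact substitution on a single variable", {
  q1 <- qubo_model(matrix(2, 1, 1))
  is1 <- qubo_to_ising(q1)
  expect_equal(is1$h, 1)
  expect_equal(is1$offset, 1)
  expect_equal(ising_energy(is1, 1), qubo_energy(q1, 1))   # 2
  expect_equal(ising_energy(is1, -1), qubo_energy(q1, 0))  # 0
})

test_that("QUBO/Ising energy identity holds exhaustively", {
  # the 16-variable example: all 65,536 states
  qubo <- tsp_to_qubo(example_tsp())
  ising <- qubo_to_ising(qubo)
  X <- quboasm:::state_bits(0:65535, 16)
  eq <- quboasm:::qubo_energies(qubo, X)
  ei <- quboasm:::ising_energies(ising, 2 * X - 1)
  expect_lt(max(abs(eq - ei)), 1e-9)

  # random 6-variable QUBOs: all 64 states, via the scalar entry points
  set.seed(17)
  for (rep in 1:5) {
    Q <- matrix(0, 6, 6)
    Q[upper.tri(Q, diag = TRUE)] <- round(stats::runif(21, -10, 10), 2)
    qubo6 <- qubo_model(Q)
    ising6 <- qubo_to_ising(qubo6)
    for (i in 0:63) {
      x <- quboasm:::state_bits(i, 6)[1, ]
      expect_equal(ising_energy(ising6, 2 * x - 1), qubo_energy(qubo6, x),
                   tolerance = 1e-9)
    }
  }
})

test_that("Ising argmin maps to the same four assignments as the QUBO argmin", {
  ising <- qubo_to_ising(tsp_to_qubo(example_tsp()))
  X <- quboasm:::state_bits(0:65535, 16)
  E <- quboasm:::ising_energies(ising, 2 * X - 1)
  minima <- apply(X[E <= min(E) + 1e-9, ], 1, paste, collapse = "")
  expect_setequal(minima, type_a_bitstrings)
  expect_error(ising_energy(ising, c(rep(1, 15), 0)), "spin")
})

test_that("the argmin set is stable under penalty scaling beyond sufficiency", {
  X <- quboasm:::state_bits(0:65535, 16)
  for (b in c(13, 20, 50, 100)) {
    qubo <- tsp_to_qubo(example_tsp(), a = 0, b = b, c = b)
    E <- quboasm:::qubo_energies(qubo, X)
    minima <- apply(X[E <= min(E) + 1e-9, , drop = FALSE], 1, paste, collapse = "")
    expect_setequal(minima, type_a_bitstrings)
  }
})

test_that("valid-assignment energy decomposes as n*a + tour cost", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(3:4, 1)
    tsp <- tsp_instance(matrix(-sample(0:9, n * n, replace = TRUE), n, n))
    a <- sample(-3:0, 1)
    qubo <- tsp_to_qubo(tsp, a = a, b = 11, c = 9)
    for (tour in enumerate_unique_tours(n)) {
      x <- encode_assignment(tour)
      expect_equal(qubo_energy(qubo, x), n * a + tour_cost(tsp, tour))
    }
  }
})

test_that("penalty_sufficient gives the n * max|w| preset", {
  expect_equal(penalty_sufficient(example_tsp()), 4 * 9)
})

test_that("COO export round-trips coefficients", {
  qubo <- tsp_to_qubo(example_tsp())
  path <- withr::local_tempfile(fileext = ".txt")
  write_coo(qubo, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# \\{")
  triples <- read.table(text = lines[-1], col.names = c("u", "v", "coef"))
  expect_equal(nrow(triples), interaction_count(qubo))  # a = 0: no diagonal lines
  for (k in sample(nrow(triples), 10)) {
    expect_equal(qubo$Q[triples$u[k] + 1, triples$v[k] + 1], triples$coef[k])
  }
})
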