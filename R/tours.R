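# Brute-force tour machinery: the oracle the QUBO/QAOA routes are
# validated against. Tours are integer vectors of 1-based node indices,
# interpreted cyclically (edge from order[k] to order[k+1], plus the
# closing edge back to order[1]).

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Enumerate start-fixed directed Hamiltonian cycles
#'
#' Returns all `(n-1)!` tours with the starting node fixed at node 1.
#' Rotations of a cycle are collapsed (a different starting city gives
#' the same cost), but *direction is not*: the overlap weights are
#' asymmetric, so a cycle and its reversal are distinct tours.
#'
#' @param n node count (>= 2).
#' @return List of integer vectors, each a permutation of `1:n`
#'   beginning with 1.
#' @examples
#' length(enumerate_unique_tours(4)) # 6
#' @export
enumerate_unique_tours <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  rest <- if (n >= 2L) seq.int(2L, n) else integer(0)
  lapply(permutations_of(rest), function(p) c(1L, p))
}

#' Cost of a tour including the closing edge
#'
#' @param tsp a `tsp_instance`.
#' @param tour integer vector, a permutation of `1:tsp$n`.
#' @return Sum of the `n` directed edge weights along the cycle.
#' @export
tour_cost <- function(tsp, tour) {
  tour <- as.integer(tour)
  if (length(tour) != tsp$n || !setequal(tour, seq_len(tsp$n))) {
    stop("tour must be a permutation of 1:n")
  }
  nxt <- c(tour[-1L], tour[1L])
  sum(tsp$weights[cbind(tour, nxt)])
}

#' All minimum-cost start-fixed tours by exhaustive enumeration
#'
#' Factorial-time brute force, guarded at `n <= max_n`. This is the
#' independent oracle the QUBO/Ising/QAOA solvers are checked against;
#' all cost ties are returned.
#'
#' @param tsp a `tsp_instance`.
#' @param max_n enumeration guard (default 10).
#' @return List of optimal tours (start-fixed representations).
#' @export
optimal_tours <- function(tsp, max_n = 10L) {
  if (tsp$n > max_n) {
    stop(sprintf("n = %d exceeds the enumeration guard (%d); use simulated_annealing() or run_qaoa()",
                 tsp$n, max_n))
  }
  tours <- enumerate_unique_tours(tsp$n)
  costs <- vapply(tours, function(t) tour_cost(tsp, t), numeric(1))
  tours[abs(costs - min(costs)) < 1e-9]
}

#' All rotations of a tour
#'
#' The `n` start-node representations of one cycle; each is an
#' equally acceptable solution of the assembly problem.
#'
#' @param tour integer vector (a permutation).
#' @return List of `length(tour)` integer vectors.
#' @export
tour_rotations <- function(tour) {
  n <- length(tour)
  lapply(seq_len(n) - 1L, function(k) tour[((seq_len(n) - 1L + k) %% n) + 1L])
}

# Canonical representative of a cycle: the rotation starting at node 1.
canonical_rotation <- function(tour) {
  k <- which(tour == min(tour))
  tour_rotations(tour)[[k]]
}
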