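# The QAOA variational loop: random-restart gradient-free minimization
# of the cost expectation over the 2*steps angles.

supported_optimizers <- c("Nelder-Mead", "BFGS", "CG", "SANN")

#' Run QAOA on a directed TSP instance
#'
#' Builds the diagonal cost Hamiltonian ([build_cost_hamiltonian()]),
#' compiles the depth-`steps` alternating ansatz, and minimizes the cost
#' expectation over the angles `(gamma_1, beta_1, ..., gamma_p, beta_p)`
#' with a gradient-free optimizer from random restarts. The statevector
#' is evaluated exactly (the diagonal cost layer is applied as a phase,
#' which equals the gate-compiled circuit; equality is covered by the
#' test suite), and expectations use exact probabilities rather than
#' shot sampling.
#'
#' @param tsp a `tsp_instance` with `n^2 <= 20` qubits.
#' @param steps QAOA depth `p` (default 1).
#' @param w assignment-pressure weight of the cost Hamiltonian
#'   (default `1e5`).
#' @param penalty co-location/repetition weight (defaults to `w`).
#' @param optimizer one of `"Nelder-Mead"` (default), `"BFGS"`, `"CG"`,
#'   `"SANN"` (passed to [stats::optim()]).
#' @param max_iter iteration cap per restart (default 200).
#' @param restarts number of random restarts (default 40).
#' @param seed integer seed controlling the restart angles.
#' @param init `"random"` (uniform in `[0, 2*pi)`) or a numeric vector
#'   of `2*steps` starting angles used for every restart.
#' @param top_k how many highest-probability basis states to retain in
#'   the result (default 10).
#' @return An object of class `qaoa_result`: `gammas`, `betas` (best
#'   angles), `expectation` (best value), `trace` (best-so-far
#'   expectation after each objective evaluation, non-increasing),
#'   `probabilities` (top-k named by bitstring), `decoded` (each top
#'   state run through [decode_assignment()]), `metadata`.
#' @export
run_qaoa <- function(tsp, steps = 1L, w = 1e5, penalty = w,
                     optimizer = "Nelder-Mead", max_iter = 200L,
                     restarts = 40L, seed = NULL, init = "random",
                     top_k = 10L) {
  stopifnot(inherits(tsp, "tsp_instance"))
  if (!optimizer %in% supported_optimizers) {
    stop(sprintf("unknown optimizer '%s'; supported: %s",
                 optimizer, paste(supported_optimizers, collapse = ", ")))
  }
  n <- tsp$n
  N <- n * n
  if (N > 20L) stop("QAOA statevector simulation is guarded at n^2 <= 20 qubits")
  steps <- as.integer(steps)
  ham <- build_cost_hamiltonian(tsp, w = w, penalty = penalty)
  diagE <- diagonal_energies(ham)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  pairs <- qubit_pairs(N)
  trace <- numeric(0)
  best_so_far <- Inf
  objective <- function(theta) {
    g <- theta[seq_len(steps)]
    b <- theta[steps + seq_len(steps)]
    st <- qaoa_state(diagE, N, g, b, pairs)
    val <- sum(Re(st * Conj(st)) * diagE)
    best_so_far <<- min(best_so_far, val)
    trace[length(trace) + 1L] <<- best_so_far
    val
  }

  best <- list(value = Inf, par = NULL)
  iters <- 0L
  for (r in seq_len(restarts)) {
    theta0 <- if (is.numeric(init)) {
      if (length(init) != 2L * steps) stop("init must supply 2*steps angles")
      init
    } else stats::runif(2L * steps, 0, 2 * pi)
    fit <- stats::optim(theta0, objective, method = optimizer,
                        control = list(maxit = max_iter))
    iters <- iters + fit$counts[["function"]]
    if (fit$value < best$value) best <- list(value = fit$value, par = fit$par)
  }

  gstar <- best$par[seq_len(steps)]
  bstar <- best$par[steps + seq_len(steps)]
  state <- qaoa_state(diagE, N, gstar, bstar, pairs)
  probs <- Re(state * Conj(state))
  ord <- order(probs, decreasing = TRUE)[seq_len(min(top_k, length(probs)))]
  top <- probs[ord]
  names(top) <- index_bitstrings(ord - 1L, N)
  decoded <- lapply(names(top), function(bs) decode_assignment(bs, n))
  res <- list(gammas = gstar, betas = bstar, expectation = best$value,
              trace = trace, probabilities = top, decoded = decoded,
              metadata = list(optimizer = optimizer, steps = steps,
                              restarts = restarts, max_iter = max_iter,
                              evaluations = iters, seed = seed,
                              w = w, penalty = penalty))
  class(res) <- "qaoa_result"
  res
}

#' @export
print.qaoa_result <- function(x, ...) {
  cat(sprintf("qaoa_result: p = %d, %s, %d restarts, %d evaluations\n",
              x$metadata$steps, x$metadata$optimizer, x$metadata$restarts,
              x$metadata$evaluations))
  cat(sprintf("best expectation: %g at gamma = (%s), beta = (%s)\n",
              x$expectation, paste(signif(x$gammas, 4), collapse = ", "),
              paste(signif(x$betas, 4), collapse = ", ")))
  cat("top states:\n")
  for (k in seq_len(min(5L, length(x$probabilities)))) {
    d <- x$decoded[[k]]
    cat(sprintf("  %s  p = %.4g  %s\n", names(x$probabilities)[k],
                x$probabilities[k],
                if (d$valid) paste("tour:", paste(d$tour - 1L, collapse = " -> "))
                else paste("invalid:", d$diagnosis)))
  }
  invisible(x)
}

#' Serialize a QAOA result to JSON
#'
#' @param res a `qaoa_result`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
qaoa_to_json <- function(res, path = NULL) {
  obj <- list(
    gammas = res$gammas, betas = res$betas, expectation = res$expectation,
    trace = res$trace,
    probabilities = as.list(res$probabilities),
    decoded = lapply(res$decoded, function(d) list(
      valid = d$valid,
      tour = if (d$valid) d$tour - 1L else NULL,
      diagnosis = d$diagnosis
    )),
    metadata = res$metadata
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
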