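# Ground-state solvers for QUBO/Ising models: exhaustive enumeration
# (the exact route) and seeded single-spin-flip Metropolis annealing
# (classical stand-in for a quantum annealer).

# Binary state matrix for 0-based state indices `idx` over N bits.
# Bit u (1-based variable u) has weight 2^(N-u), so ascending idx
# enumerates configuration strings in lexicographic order.
state_bits <- function(idx, N) {
  X <- matrix(0L, length(idx), N)
  for (u in seq_len(N)) {
    X[, u] <- bitwAnd(idx %/% (2^(N - u)), 1L)
  }
  X
}

config_keys <- function(X) {
  apply(X, 1L, paste, collapse = "")
}

#' Solution sample set
#'
#' Ordered collection of solver outputs: one row of `configurations`
#' per distinct state, with its energy and multiplicity (how many times
#' a sampler produced it; 1 for exhaustive enumeration). Records are
#' sorted by ascending energy, ties broken lexicographically on the
#' 0/1 form of the configuration, so ordering is total and identical
#' for a QUBO and its Ising transform.
#'
#' @param configurations numeric matrix, one state per row (0/1 or -1/+1
#'   per `convention`).
#' @param energy numeric vector of per-row energies.
#' @param multiplicity integer vector (default all 1).
#' @param convention `"binary"` or `"spin"`.
#' @param metadata solver provenance (name, seed, schedule, ...).
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(configurations, energy, multiplicity = NULL,
                       convention = c("binary", "spin"), metadata = list()) {
  convention <- match.arg(convention)
  configurations <- as.matrix(configurations)
  if (is.null(multiplicity)) multiplicity <- rep(1L, nrow(configurations))
  stopifnot(nrow(configurations) == length(energy),
            length(multiplicity) == length(energy))
  Xbin <- if (convention == "spin") (configurations + 1) / 2 else configurations
  ord <- order(round(energy / 1e-9) * 1e-9, config_keys(Xbin))
  ss <- list(configurations = configurations[ord, , drop = FALSE],
             energy = energy[ord],
             multiplicity = as.integer(multiplicity[ord]),
             convention = convention,
             metadata = metadata)
  class(ss) <- "sample_set"
  ss
}

#' @export
print.sample_set <- function(x, n = 10L, ...) {
  cat(sprintf("sample_set (%s): %d distinct states, best energy %g\n",
              x$convention, nrow(x$configurations), x$energy[1]))
  m <- min(n, nrow(x$configurations))
  for (k in seq_len(m)) {
    cat(sprintf("  [%s]  E = %g  x%d\n",
                paste(x$configurations[k, ], collapse = ""),
                x$energy[k], x$multiplicity[k]))
  }
  if (nrow(x$configurations) > m) cat(sprintf("  ... %d more\n", nrow(x$configurations) - m))
  invisible(x)
}

model_size <- function(model) {
  if (inherits(model, "qubo_model")) model$N
  else if (inherits(model, "ising_model")) model$N
  else stop("model must be a qubo_model or ising_model")
}

#' Exhaustive ground-state search
#'
#' Enumerates every one of the `2^N` configurations of a QUBO or Ising
#' model and returns either the complete set of global minima (all
#' degenerate ties -- the four-read instance has 4), the `k`
#' lowest-energy states, or the full spectrum. Deterministic; energies
#' are evaluated vectorized in chunks of at most `2^16` states.
#'
#' @param model a `qubo_model` or `ising_model`.
#' @param keep `"minima"` (default: every global minimum), a positive
#'   integer `k` (the `k` lowest-energy states), or `"all"` (full
#'   spectrum; guarded at `N <= 20`).
#' @param max_N enumeration guard (default 24, i.e. 16.7M states).
#' @return A [sample_set()]; binary rows for a QUBO, spin rows for an
#'   Ising model.
#' @export
solve_exact <- function(model, keep = "minima", max_N = 24L) {
  N <- model_size(model)
  if (N > max_N) {
    stop(sprintf("N = %d exceeds the exhaustive-enumeration guard (N <= %d)", N, max_N))
  }
  is_qubo <- inherits(model, "qubo_model")
  spectrum <- identical(keep, "all")
  if (spectrum && N > 20L) stop("full spectrum is guarded at N <= 20")
  topk <- if (is.numeric(keep)) as.integer(keep) else NA_integer_
  if (is.numeric(keep) && topk < 1L) stop("keep must be a positive integer, \"minima\" or \"all\"")

  chunk <- 2^min(N, 16L)
  nstates <- 2^N
  bestX <- NULL; bestE <- numeric(0)
  for (start in seq(0, nstates - 1, by = chunk)) {
    idx <- start + seq_len(chunk) - 1
    X <- state_bits(idx, N)
    E <- if (is_qubo) qubo_energies(model, X) else ising_energies(model, 2 * X - 1)
    if (spectrum) {
      bestX <- rbind(bestX, X); bestE <- c(bestE, E)
      next
    }
    if (!is.na(topk)) {
      keepn <- min(topk, length(E))
      sel <- order(E)[seq_len(keepn)]
    } else {
      sel <- which(E <= min(E) + 1e-9)
    }
    bestX <- rbind(bestX, X[sel, , drop = FALSE])
    bestE <- c(bestE, E[sel])
    # prune the running pool
    if (!is.na(topk)) {
      sel <- order(bestE)[seq_len(min(topk, length(bestE)))]
    } else {
      sel <- which(bestE <= min(bestE) + 1e-9)
    }
    bestX <- bestX[sel, , drop = FALSE]
    bestE <- bestE[sel]
  }
  conf <- if (is_qubo) bestX else 2 * bestX - 1
  sample_set(conf, bestE,
             convention = if (is_qubo) "binary" else "spin",
             metadata = list(solver = "exact", keep = keep, N = N))
}

#' Seeded classical simulated annealing
#'
#' Classical stand-in for a quantum annealer: `n_samples` independent
#' single-spin-flip Metropolis anneals from uniform random spin starts,
#' with inverse temperature swept over `sweeps` full-lattice sweeps.
#' Fully deterministic given `seed`; identical final configurations are
#' aggregated with multiplicities.
#'
#' @param model an `ising_model` (a `qubo_model` is transformed via
#'   [qubo_to_ising()] first; results are reported as spins either way).
#' @param n_samples number of independent anneals (default 1000).
#' @param sweeps Metropolis sweeps per anneal (default 1000).
#' @param beta_start,beta_end inverse-temperature schedule endpoints
#'   (defaults 0.1 and 10).
#' @param schedule `"geometric"` (default) or `"linear"` interpolation.
#' @param seed integer RNG seed (recorded in the output metadata).
#' @return A [sample_set()] in spin convention; energies include the
#'   Ising offset so they are directly comparable to QUBO energies.
#' @export
simulated_annealing <- function(model, n_samples = 1000L, sweeps = 1000L,
                                beta_start = 0.1, beta_end = 10,
                                schedule = c("geometric", "linear"),
                                seed = NULL) {
  schedule <- match.arg(schedule)
  ising <- if (inherits(model, "qubo_model")) qubo_to_ising(model) else model
  if (!inherits(ising, "ising_model")) stop("model must be a qubo_model or ising_model")
  n_samples <- as.integer(n_samples); sweeps <- as.integer(sweeps)
  if (n_samples < 1L || sweeps < 1L) stop("n_samples and sweeps must be >= 1")
  if (!is.finite(beta_start) || !is.finite(beta_end) || beta_start <= 0 || beta_end <= 0) {
    stop("beta schedule endpoints must be finite and positive")
  }
  N <- ising$N
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  betas <- if (sweeps == 1L) beta_end
  else if (schedule == "geometric") beta_start * (beta_end / beta_start)^((seq_len(sweeps) - 1) / (sweeps - 1))
  else beta_start + (beta_end - beta_start) * (seq_len(sweeps) - 1) / (sweeps - 1)

  Jsym <- ising$J + t(ising$J)
  S <- matrix(sample(c(-1, 1), n_samples * N, replace = TRUE), n_samples, N)
  for (t in seq_len(sweeps)) {
    beta <- betas[t]
    for (q in seq_len(N)) {
      f <- as.numeric(S %*% Jsym[, q]) + ising$h[q]
      dE <- -2 * S[, q] * f
      acc <- dE <= 0 | stats::runif(n_samples) < exp(-beta * dE)
      S[acc, q] <- -S[acc, q]
    }
  }
  E <- ising_energies(ising, S)
  key <- config_keys((S + 1) / 2)
  first <- !duplicated(key)
  mult <- as.integer(table(key)[key[first]])
  sample_set(S[first, , drop = FALSE], E[first], mult,
             convention = "spin",
             metadata = list(solver = "simulated_annealing", seed = seed,
                             n_samples = n_samples, sweeps = sweeps,
                             schedule = schedule,
                             beta = c(beta_start, beta_end)))
}

#' Serialize a sample set to JSON
#'
#' @param ss a [sample_set()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @param top_k number of records to keep (default all).
#' @return JSON string (invisibly when written to `path`).
#' @export
sampleset_to_json <- function(ss, path = NULL, top_k = Inf) {
  m <- min(top_k, nrow(ss$configurations))
  obj <- list(
    convention = ss$convention,
    records = lapply(seq_len(m), function(k) list(
      configuration = paste(ss$configurations[k, ], collapse = if (ss$convention == "spin") "," else ""),
      energy = ss$energy[k],
      multiplicity = ss$multiplicity[k]
    )),
    metadata = ss$metadata
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
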