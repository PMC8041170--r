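# Decoding solver output back into tours and stitching reads into the
# assembled sequence.

#' Decode a QUBO/Ising configuration into a tour
#'
#' Interprets a length-`n^2` configuration as the assignment matrix
#' `x[i, p]` ("node i occupies slot p", variable index `i*n + p`,
#' 0-based). When the matrix is a permutation matrix the tour visits the
#' nodes in slot order; otherwise the configuration is reported invalid
#' with a diagnosis (empty/double-booked slots, unassigned/relocated
#' nodes). Invalid configurations are never silently repaired: a repair
#' policy would mask encoding or penalty defects.
#'
#' @param configuration binary vector, spin vector (mapped through
#'   `x = (1 + s) / 2`), or a 0/1 bitstring.
#' @param n node count (`length(configuration) == n^2`).
#' @return A list: `valid` (flag), `tour` (integer vector of 1-based
#'   node indices, or `NULL`), `assignment` (the `n x n` matrix),
#'   `diagnosis` (`NULL` when valid).
#' @examples
#' decode_assignment("1000010000100001", 4)$tour # 1 2 3 4
#' @export
decode_assignment <- function(configuration, n) {
  n <- as.integer(n)
  if (is.character(configuration) && length(configuration) == 1L) {
    configuration <- as.integer(strsplit(configuration, "", fixed = TRUE)[[1]])
  }
  x <- as.numeric(configuration)
  if (length(x) != n * n) {
    stop(sprintf("configuration must have length n^2 = %d", n * n))
  }
  if (all(x %in% c(-1, 1)) && any(x == -1)) x <- (1 + x) / 2
  if (!all(x %in% c(0, 1))) stop("configuration must be binary (0/1) or spin (-1/+1)")
  M <- matrix(x, n, n, byrow = TRUE)  # rows = nodes, cols = time slots
  rs <- rowSums(M); cs <- colSums(M)
  problems <- character(0)
  if (any(cs == 0)) problems <- c(problems, sprintf("empty slot(s) %s", paste(which(cs == 0) - 1L, collapse = ",")))
  if (any(cs > 1)) problems <- c(problems, sprintf("double-booked slot(s) %s", paste(which(cs > 1) - 1L, collapse = ",")))
  if (any(rs == 0)) problems <- c(problems, sprintf("unassigned node(s) %s", paste(which(rs == 0) - 1L, collapse = ",")))
  if (any(rs > 1)) problems <- c(problems, sprintf("relocated node(s) %s", paste(which(rs > 1) - 1L, collapse = ",")))
  if (length(problems)) {
    return(list(valid = FALSE, tour = NULL, assignment = M,
                diagnosis = paste(problems, collapse = "; ")))
  }
  tour <- apply(M, 2L, which.max)
  list(valid = TRUE, tour = as.integer(tour), assignment = M, diagnosis = NULL)
}

#' Build the assignment vector of a tour
#'
#' Inverse of [decode_assignment()] for valid tours: useful for checking
#' round trips and for computing the QUBO energy of a known tour.
#'
#' @param tour integer vector of 1-based node indices.
#' @return Binary vector of length `n^2`.
#' @export
encode_assignment <- function(tour) {
  n <- length(tour)
  x <- numeric(n * n)
  for (p in seq_len(n)) x[(tour[p] - 1L) * n + p] <- 1
  x
}

#' Stitch reads along a tour into an assembled sequence
#'
#' Linear overlap-layout-consensus stitch: start from the tour's first
#' read and append each subsequent read after trimming its exact
#' suffix-prefix overlap with the previous one. The closing (cycle)
#' overlap between the last and first read is reported but not trimmed;
#' set `circular = TRUE` to trim it from the end and obtain one period
#' of the circular sequence.
#'
#' @param readset a [read_set()].
#' @param tour integer vector of 1-based read indices (a permutation or
#'   a subset without repeats).
#' @param circular trim the closing overlap (default `FALSE`).
#' @param provenance optional solver metadata carried into the result.
#' @return An object of class `assembly_result`: `tour`, `sequence`,
#'   `total_overlap` (sum of the internal overlaps), `closing_overlap`,
#'   `assembled_length`, `valid`, `provenance`. For a linear stitch
#'   `assembled_length == sum(read lengths) - total_overlap`.
#' @export
stitch <- function(readset, tour, circular = FALSE, provenance = NULL) {
  stopifnot(inherits(readset, "read_set"))
  tour <- as.integer(tour)
  if (anyDuplicated(tour) || any(tour < 1L) || any(tour > length(readset$reads))) {
    stop("tour must be distinct 1-based read indices")
  }
  reads <- readset$reads[tour]
  seqn <- reads[1]
  total <- 0L
  if (length(reads) > 1L) {
    for (k in 2:length(reads)) {
      ov <- pairwise_overlap(reads[k - 1L], reads[k])
      total <- total + ov
      seqn <- paste0(seqn, substr(reads[k], ov + 1L, nchar(reads[k])))
    }
  }
  closing <- if (length(reads) > 1L) pairwise_overlap(reads[length(reads)], reads[1]) else 0L
  if (circular && closing > 0L) seqn <- substr(seqn, 1L, nchar(seqn) - closing)
  res <- list(tour = tour, sequence = seqn, total_overlap = total,
              closing_overlap = closing, assembled_length = nchar(seqn),
              circular = circular, valid = TRUE, provenance = provenance)
  class(res) <- "assembly_result"
  res
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result: tour %s\n", paste(x$tour - 1L, collapse = " -> ")))
  cat(sprintf("  sequence (%d nt%s): %s\n", x$assembled_length,
              if (x$circular) ", circularized" else "", x$sequence))
  cat(sprintf("  internal overlap %d, closing overlap %d\n",
              x$total_overlap, x$closing_overlap))
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' End-to-end assembly pipeline
#'
#' Runs the full chain: reads -> overlap graph -> directed TSP -> QUBO
#' (and Ising transform) -> solver -> decoded tours -> stitched
#' sequences, and returns a report. Exactly one read source must be
#' given: an explicit character vector, a FASTA path, or the circular
#' generator (`genome` + `offsets` + `read_length`).
#'
#' @param reads character vector of reads.
#' @param fasta path to a FASTA file.
#' @param genome,offsets,read_length arguments of
#'   [generate_circular_reads()].
#' @param a,b,c QUBO encoding parameters (see [tsp_to_qubo()]).
#' @param solver `"exact"` (default), `"sa"` (simulated annealing) or
#'   `"qaoa"`.
#' @param n_samples,sweeps simulated-annealing parameters.
#' @param steps,w,restarts,max_iter,optimizer QAOA parameters.
#' @param seed seed for the stochastic solvers.
#' @param top_k states retained from stochastic solvers (default 10).
#' @param circular also report the circularized sequence of the best
#'   tour (default `FALSE`).
#' @param out optional path for a JSON report.
#' @return A list report: `reads`, `overlaps`, `qubo` and `ising`
#'   summaries, `solver` outputs, and `solutions` -- one entry per
#'   co-minimal decoded tour with its stitched sequence; the
#'   lexicographically smallest tour is flagged `canonical`.
#' @export
run_pipeline <- function(reads = NULL, fasta = NULL, genome = NULL,
                         offsets = NULL, read_length = NULL,
                         a = 0, b = 13, c = 13,
                         solver = c("exact", "sa", "qaoa"),
                         n_samples = 1000L, sweeps = 1000L,
                         steps = 1L, w = 1e5, restarts = 40L,
                         max_iter = 200L, optimizer = "Nelder-Mead",
                         seed = NULL, top_k = 10L, circular = FALSE,
                         out = NULL) {
  solver <- match.arg(solver)
  rs <- with_stage("reads", {
    if (!is.null(reads)) read_set(reads)
    else if (!is.null(fasta)) read_fasta(fasta)
    else if (!is.null(genome)) generate_circular_reads(genome, offsets, read_length)
    else stop("supply reads, fasta, or genome/offsets/read_length")
  })
  tsp <- with_stage("overlap", reads_to_tsp(rs))
  qubo <- with_stage("encode", tsp_to_qubo(tsp, a = a, b = b, c = c))
  ising <- with_stage("encode", qubo_to_ising(qubo))

  solutions <- list()
  solver_report <- NULL
  if (solver == "exact") {
    ss <- with_stage("solve-exact", solve_exact(qubo))
    solver_report <- list(name = "exact", best_energy = ss$energy[1],
                          n_minima = nrow(ss$configurations))
    for (k in seq_len(nrow(ss$configurations))) {
      solutions[[k]] <- list(configuration = ss$configurations[k, ],
                             energy = ss$energy[k])
    }
  } else if (solver == "sa") {
    ss <- with_stage("solve-sa",
                     simulated_annealing(ising, n_samples = n_samples,
                                         sweeps = sweeps, seed = seed))
    solver_report <- list(name = "simulated_annealing", best_energy = ss$energy[1],
                          metadata = ss$metadata)
    best <- which(ss$energy <= ss$energy[1] + 1e-9)
    for (k in best) {
      solutions[[length(solutions) + 1L]] <-
        list(configuration = (ss$configurations[k, ] + 1) / 2,
             energy = ss$energy[k], multiplicity = ss$multiplicity[k])
    }
  } else {
    qr <- with_stage("solve-qaoa",
                     run_qaoa(tsp, steps = steps, w = w, optimizer = optimizer,
                              max_iter = max_iter, restarts = restarts,
                              seed = seed, top_k = top_k))
    solver_report <- list(name = "qaoa", expectation = qr$expectation,
                          gammas = qr$gammas, betas = qr$betas,
                          metadata = qr$metadata)
    for (k in seq_along(qr$decoded)) {
      if (qr$decoded[[k]]$valid) {
        solutions[[length(solutions) + 1L]] <-
          list(configuration = encode_assignment(qr$decoded[[k]]$tour),
               probability = unname(qr$probabilities[k]))
      }
    }
  }

  decoded <- with_stage("decode", lapply(solutions, function(sol) {
    d <- decode_assignment(sol$configuration, tsp$n)
    sol$valid <- d$valid
    sol$tour <- d$tour
    sol$diagnosis <- d$diagnosis
    sol
  }))
  tours <- Filter(function(s) s$valid, decoded)
  keys <- vapply(tours, function(s) paste(s$tour, collapse = ","), character(1))
  canonical_key <- if (length(keys)) sort(keys)[1] else NA_character_

  stitched <- with_stage("assemble", lapply(tours, function(sol) {
    asm <- stitch(rs, sol$tour, provenance = solver_report$name)
    list(tour = sol$tour - 1L,
         energy = sol$energy,
         cost = tour_cost(tsp, sol$tour),
         sequence = asm$sequence,
         assembled_length = asm$assembled_length,
         total_overlap = asm$total_overlap,
         closing_overlap = asm$closing_overlap,
         circular_sequence = if (circular)
           stitch(rs, sol$tour, circular = TRUE)$sequence else NULL,
         canonical = identical(paste(sol$tour, collapse = ","), canonical_key))
  }))

  invalid <- Filter(function(s) !s$valid, decoded)
  report <- list(
    reads = rs$reads, labels = rs$labels,
    overlaps = -tsp$weights,
    qubo = list(n = qubo$n, N = qubo$N, params = as.list(qubo$params),
                interactions = interaction_count(qubo)),
    ising = list(offset = ising$offset),
    solver = solver_report,
    solutions = stitched,
    invalid = lapply(invalid, function(s) list(
      configuration = paste(s$configuration, collapse = ""),
      diagnosis = s$diagnosis)),
    seed = seed
  )
  if (!is.null(out)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, null = "null"), out)
  }
  report
}
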