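#' Ordered, deduplicated set of DNA reads
#'
#' Container for the reads entering the assembly pipeline. Reads are
#' uppercase strings over the alphabet A/C/G/T; duplicates are removed
#' (first occurrence kept) and the remaining order is stable: read `i`
#' in the set is node `i` in every downstream graph, QUBO variable block
#' and tour.
#'
#' @param reads character vector of DNA sequences.
#' @param labels optional per-read identifiers; defaults to
#'   `"read 0"`, `"read 1"`, ... in input order (after deduplication).
#' @return An object of class `read_set` with elements `reads`, `labels`
#'   and `dropped` (labels/indices of duplicate records that were removed).
#' @examples
#' rs <- read_set(c("ATGGCGTGCA", "GCGTGCAATG"))
#' length(rs$reads)
#' @export
read_set <- function(reads, labels = NULL) {
  if (length(reads) == 0L) stop("at least one read is required")
  reads <- toupper(as.character(reads))
  validate_dna(reads, what = if (is.null(labels)) paste("read", seq_along(reads) - 1L) else labels)
  if (is.null(labels)) labels <- paste("read", seq_along(reads) - 1L)
  if (length(labels) != length(reads)) stop("labels must match reads in length")
  dup <- duplicated(reads)
  dropped <- labels[dup]
  rs <- list(reads = reads[!dup], labels = labels[!dup], dropped = dropped)
  class(rs) <- "read_set"
  rs
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads\n", length(x$reads)))
  for (i in seq_along(x$reads)) cat(sprintf("  %s: %s\n", x$labels[i], x$reads[i]))
  if (length(x$dropped)) cat("dropped duplicates:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# Strict alphabet check: uppercase A/C/G/T only. IUPAC ambiguity codes and
# gaps are rejected (exact-match overlap scoring is meaningless on them);
# the offending record and character position are named.
validate_dna <- function(reads, what = paste("read", seq_along(reads) - 1L)) {
  for (i in seq_along(reads)) {
    r <- reads[i]
    if (!nzchar(r)) stop(sprintf("%s is empty", what[i]))
    bad <- regexpr("[^ACGT]", r)
    if (bad > 0L) {
      stop(sprintf("%s contains invalid symbol '%s' at position %d (only A/C/G/T allowed)",
                   what[i], substr(r, bad, bad), bad))
    }
  }
  invisible(TRUE)
}

#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a
#' [read_set()]. Sequences are uppercased, validated against the strict
#' A/C/G/T alphabet, and deduplicated keeping the first occurrence.
#'
#' @param path path to a FASTA file.
#' @return A `read_set`; `$dropped` records the headers of duplicate
#'   records that were removed.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop(sprintf("FASTA parse error in %s: file is empty", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA parse error at line %d of %s: expected '>' header before sequence data",
                 nonblank[1], path))
  }
  headers <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (k in nonblank) {
    ln <- trimws(lines[k])
    if (startsWith(ln, ">")) {
      headers <- c(headers, sub("^>\\s*", "", ln))
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      seqs[cur] <- paste0(seqs[cur], ln)
    }
  }
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop(sprintf("FASTA parse error in %s: record '%s' has no sequence", path, headers[empty[1]]))
  }
  read_set(seqs, labels = headers)
}

#' Write a sequence (or read set) to FASTA
#'
#' @param x a `read_set`, or a named/unnamed character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "read_set")) {
    seqs <- x$reads; names(seqs) <- x$labels
  } else {
    seqs <- as.character(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs) - 1L)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate reads as fixed-length windows of a circular genome
#'
#' Emulates error-free shotgun reads from a circular template: read `k`
#' is the window of `read_length` bases starting at `offsets[k]`
#' (0-based), with indices wrapping around the end of the genome.
#' Consecutive offsets a step `s` apart therefore share an exact
#' suffix-prefix overlap of `read_length - s` (absent coincidental
#' repeats), which is the structure the overlap-layout-consensus
#' encoding is designed to recover.
#'
#' @param genome template sequence over A/C/G/T (treated as circular).
#' @param offsets integer vector of 0-based start positions, each in
#'   `[0, nchar(genome))`.
#' @param read_length window length (>= 1).
#' @return A [read_set()] of the windows in offset order, deduplicated.
#' @examples
#' generate_circular_reads("ATGGCGTGCA", c(0, 3, 6, 9), 10)
#' @export
generate_circular_reads <- function(genome, offsets, read_length) {
  genome <- toupper(as.character(genome))
  validate_dna(genome, what = "genome")
  if (length(offsets) == 0L) stop("offsets must be a nonempty integer vector")
  offsets <- as.integer(offsets)
  g <- nchar(genome)
  if (any(offsets < 0L | offsets >= g)) stop(sprintf("offsets must lie in [0, %d)", g))
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  chars <- strsplit(genome, "", fixed = TRUE)[[1]]
  reads <- vapply(offsets, function(o) {
    idx <- ((o + seq_len(read_length) - 1L) %% g) + 1L
    paste(chars[idx], collapse = "")
  }, character(1))
  read_set(reads)
}

#' Maximal exact suffix-prefix overlap between two reads
#'
#' Returns the largest `k` with `0 <= k <= min(nchar(a), nchar(b)) - 1`
#' such that the last `k` characters of `a` equal the first `k`
#' characters of `b`. The cap at `min - 1` excludes full containment:
#' a read never overlaps another over its whole length (duplicates are
#' removed upstream, so the identical-read case does not arise).
#'
#' @param a,b validated read strings.
#' @return Integer overlap length (possibly 0).
#' @examples
#' pairwise_overlap("ATGGCGTGCA", "GCGTGCAATG") # 7
#' @export
pairwise_overlap <- function(a, b) {
  kmax <- min(nchar(a), nchar(b)) - 1L
  na <- nchar(a)
  for (k in seq.int(kmax, 1L)) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(as.integer(k))
  }
  0L
}

#' Build the directed TSP instance from a read set
#'
#' Computes the exact suffix-prefix overlap for every ordered read pair
#' and sets the directed edge weight `i -> j` to the *negated* overlap,
#' so that the minimum-weight Hamiltonian cycle is the maximum-overlap
#' (shortest-assembly) read ordering. The graph is complete and directed;
#' zero-overlap edges are kept with weight 0.
#'
#' @param readset a [read_set()] with at least two reads.
#' @return An object of class `tsp_instance`: `n` (node count),
#'   `weights` (`n x n` matrix, diagonal fixed at 0, entry `[i, j]` the
#'   weight of edge `i -> j`) and `labels`.
#' @export
reads_to_tsp <- function(readset) {
  stopifnot(inherits(readset, "read_set"))
  n <- length(readset$reads)
  if (n < 2L) stop("at least 2 distinct reads are required to build a TSP instance")
  w <- matrix(0, n, n, dimnames = list(readset$labels, readset$labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w[i, j] <- -pairwise_overlap(readset$reads[i], readset$reads[j])
    }
  }
  tsp <- list(n = n, weights = w, labels = readset$labels)
  class(tsp) <- "tsp_instance"
  tsp
}

#' Construct a TSP instance from an explicit weight matrix
#'
#' Low-level constructor used by the solvers' tests and by callers that
#' already have a directed weight matrix (weights need not come from
#' read overlaps and need not be symmetric).
#'
#' @param weights square numeric matrix; the diagonal is forced to 0.
#' @param labels optional node names.
#' @return A `tsp_instance`.
#' @export
tsp_instance <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights) || n < 2L) stop("weights must be a square matrix with n >= 2")
  diag(weights) <- 0
  if (is.null(labels)) labels <- paste("node", seq_len(n) - 1L)
  dimnames(weights) <- list(labels, labels)
  tsp <- list(n = n, weights = weights, labels = labels)
  class(tsp) <- "tsp_instance"
  tsp
}

#' @export
print.tsp_instance <- function(x, ...) {
  cat(sprintf("tsp_instance: %d nodes, directed complete graph\n", x$n))
  print(x$weights)
  invisible(x)
}

#' Serialize a read set and its overlap matrix to JSON
#'
#' @param readset a [read_set()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
readset_to_json <- function(readset, path = NULL) {
  tsp <- if (length(readset$reads) >= 2L) reads_to_tsp(readset) else NULL
  obj <- list(
    labels = readset$labels,
    reads = readset$reads,
    overlaps = if (!is.null(tsp)) -tsp$weights else NULL
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
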