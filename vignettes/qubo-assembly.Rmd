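---
title: "De novo assembly as a QUBO: model, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo assembly as a QUBO: model, solvers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quboasm)
```

## The problem and the model

`quboasm` reconstructs a sequence from error-free DNA reads without a
reference, by the overlap-layout-consensus (OLC) route, formulated so
that the layout step can be handed to annealing-style optimizers:

1. **Overlap.** For every ordered pair of reads $(i, j)$ the maximal
   exact suffix-prefix overlap $o_{ij}$ is computed: the largest $k <
   \min(|r_i|, |r_j|)$ such that the last $k$ bases of $r_i$ equal the
   first $k$ bases of $r_j$. The cap excludes full containment; the
   identical-read case cannot arise because duplicates are removed on
   input. Setting the directed edge weight $w_{ij} = -o_{ij}$ turns
   maximum-overlap layout into a *directed traveling salesman problem*
   (TSP): the minimum-weight Hamiltonian cycle orders the reads so that
   the stitched sequence is shortest.

2. **QUBO encoding.** With $n$ reads, binary variables
   $x_{i,p} \in \{0,1\}$ ("node $i$ occupies slot $p$ of the cycle"),
   $N = n^2$ in total, the objective is
   $$ y = \sum_u Q_{uu} x_u + \sum_{u<v} Q_{uv} x_u x_v $$
   with four coefficient classes: a diagonal bias $a$ per variable, a
   penalty $b$ on every pair of nodes sharing a slot, a penalty $c$ on
   every pair of slots sharing a node, and the edge weight $w_{ij}$ on
   the pair $\{(i,p), (j,(p{+}1) \bmod n)\}$ for every slot $p$ — the
   modulo makes the encoding a cycle. At a valid permutation assignment
   the penalties vanish and $y = n a + \text{tour cost}$, which is the
   cross-module identity the test suite asserts exactly.

3. **Solvers.** Three routes to the ground state: exhaustive
   enumeration (`solve_exact`, the reference), classical simulated
   annealing (`simulated_annealing`, standing in for a quantum
   annealer), and QAOA on a dense statevector simulator (`run_qaoa`).

4. **Decode and stitch.** Ground-state configurations are decoded back
   into tours (`decode_assignment`) and reads are concatenated with
   their overlaps trimmed (`stitch`).

## Parameters that matter

* **`a` (diagonal bias), default 0.** With negative edge weights the
  path-cost terms already reward occupancy, so no explicit reward is
  needed. Degenerate corner: on an instance whose weights are all zero
  and with `a = 0`, every penalty-free *partial* assignment (empty,
  singletons) ties with the permutations at $y = 0$; a negative `a`
  breaks that tie. The tests pin both behaviours.
* **`b`, `c` (constraint penalties), default 13.** Sufficient values
  for the bundled four-read example; sweeping integer values upward,
  the argmin set collapses to exactly the four optimal-tour assignments
  from `b = c = 7` on (the acceptance report computes this). The
  instance-independent preset $n \cdot \max |w_{ij}|$ is available as
  `penalty_sufficient()`. Penalties beyond sufficiency do not move the
  argmin (property-tested at 13, 20, 50, 100).
* **`w` (QAOA assignment pressure), default `1e5`.** The cost
  Hamiltonian's single-$Z$ pressure term and the co-location/repetition
  penalty weight share this symbol and default; they are independently
  configurable (`w`, `penalty`) because their relative scale against
  the $O(10)$ edge weights dominates the optimization landscape.
* **Annealing schedule, default 1000 sweeps, geometric
  $\beta: 0.1 \to 10$.** Standard single-spin-flip Metropolis settings
  for binary quadratic models of this size; with 1000 samples the
  16-spin example reaches the exact minimum reliably at fixed seeds.
* **QAOA loop, defaults depth $p = 1$, Nelder-Mead, 40 restarts,
  200 iterations/restart, angles uniform in $[0, 2\pi)$.** Expectations
  use the exact probability vector (`shots = 0`); shot-based sampling
  is available through `sample_counts()`.

## What the synthetic generator emulates — and what it does not

`generate_circular_reads()` extracts fixed-length windows at chosen
offsets from a *circular* template, so consecutive windows share exact
suffix-prefix overlaps of `read_length - step`. This reproduces the
idealized conditions of the encoding: error-free reads, single strand,
exact overlaps, complete coverage. It does **not** emulate sequencing
error, reverse-complement reads, quality scores, uneven coverage, or
repeats longer than a read. A green test therefore establishes that the
encoding, transforms and solvers are mutually consistent and recover
the planted circular sequence — not that the method assembles realistic
sequencing data.

## Numerical choices

* **Single-count upper-triangular Q.** Each unordered pair's total
  coefficient is stored once ($u < v$). A symmetric matrix with full
  entries would double every pairwise term; single-count makes a valid
  tour's energy equal its tour cost exactly and reproduces the
  $2 n^2 (n-1)$ interaction census. `symmetrize()` provides the
  half-weight symmetric view for export.
* **$n = 2$ collision.** The two directions of an edge then map to the
  same variable pair and their weights are summed — the only consistent
  additive rule. The distinct-pair census is 6 there, below the
  no-collision closed form 8, which holds for $n \ge 3$.
* **QUBO→Ising.** The exact substitution $x = (1+s)/2$ gives
  $h_u = Q_{uu}/2 + \sum_{v} Q_{uv}/4$, $J_{uv} = Q_{uv}/4$ and a
  constant offset; correctness is enforced by an exhaustive
  energy-identity test over all $2^{16}$ states at $10^{-9}$, not by
  matching any printed pseudo-code (whose $h$ update rule is
  algebraically inconsistent).
* **Gate conventions.** $R_Z(\theta) = e^{-i\theta Z/2}$,
  $R_X(\theta) = e^{-i\theta X/2}$; a cost term $c\,Z\!\cdots$ compiles
  to $\theta = 2c\gamma$ so one cost block implements
  $e^{-i\gamma H_C}$ exactly. Bit 0 maps to $Z$-eigenvalue $+1$; qubit
  $q = i n + p$ is the $q$-th character of the bitstring (leftmost =
  qubit 0).
* **Fast path vs gate path.** `run_qaoa` applies the (diagonal) cost
  layer as the phase $e^{-i\gamma E_x}$ and the mixer as per-qubit
  $R_X$; `simulate_statevector()` is the independent gate-by-gate
  route, checked against a dense Kronecker-product oracle on up to 4
  qubits and against the fast path on the 16-qubit instance at random
  angles ($10^{-9}$). All-identity words would differ by a global phase
  only; none arise in this Hamiltonian.
* **Ties and tolerances.** Energy comparisons use $10^{-9}$ absolute;
  minima grouping takes every tie (the example has 4 degenerate ground
  states). Sample sets order by energy, then lexicographically on the
  0/1 form of the configuration, so ordering is total and identical
  across the QUBO and Ising representations.
* **Guards.** Exhaustive enumeration at $N \le 24$ (chunked, $2^{16}$
  states at a time), full-spectrum retention at $N \le 20$, statevector
  simulation at $N \le 20$ qubits; factorial tour enumeration at
  $n \le 10$.

## Design choices where the design was open

* **Invalid configurations are reported, never repaired.** A decoded
  state that is not a permutation matrix comes back with a diagnosis
  (empty/double-booked slot, unassigned/relocated node). Repair
  policies would mask penalty miscalibration.
* **Linear stitch; closing overlap reported, not trimmed.** Downstream
  consumers expect a linear sequence; `circular = TRUE` trims the
  closing overlap to recover one period of a circular template. Because
  the closing edge is *not* trimmed, rotations of the same optimal
  cycle can stitch to different lengths; all co-minimal solutions are
  reported and the lexicographically smallest tour is flagged
  canonical.
* **Reverse-complement overlaps are not considered.** Reads are treated
  as given, single strand; two-strand OLC is out of scope.
* **Randomness.** Every stochastic routine takes an explicit seed,
  records it in its output, and restores the caller's RNG state.

## Known limitations

* Exact overlaps only: one sequencing error at a junction breaks the
  layout; there is no consensus/polishing stage.
* The $n^2$-variable encoding limits exhaustive validation to toy
  instances ($n \le 4$ for the $2^{16}$-state sweep) and statevector
  QAOA to $n^2 \le 20$ qubits.
* Depth-1 QAOA on this landscape routinely settles at suboptimal
  expectations; the suite asserts improvement properties (non-increasing
  best-so-far trace, no worse than the zero-angle expectation), not
  solution quality. In the test suite the 40-restart run uses a reduced
  per-restart iteration cap (25 instead of 200) purely for runtime; the
  asserted properties do not depend on the cap.
* Simulated annealing makes no claim of emulating any hardware
  annealer's sampling statistics, auto-scaling or noise.
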