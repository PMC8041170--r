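# quboasm

Reference-free (de novo) DNA assembly by overlap-layout-consensus,
encoded as a directed traveling-salesman problem, reduced to a
QUBO/Ising model, and solved three ways: exhaustive enumeration,
seeded classical simulated annealing (a stand-in for a quantum
annealer), and a depth-`p` QAOA variational loop on a dense
statevector simulator. The decoded ground states are stitched back
into the assembled sequence.

**Who it is for:** bioinformaticians and quantum-computing researchers
who want a small, fully inspectable, end-to-end pipeline connecting a
classic genomics problem to annealing-style optimization — every stage
(overlap graph, QUBO matrix, Ising transform, Pauli cost Hamiltonian,
ansatz, sample sets) is a first-class, testable object.

## The model

For reads `r_1..r_n`, the maximal exact suffix-prefix overlap `o_ij`
defines a complete directed graph with edge weights `w_ij = -o_ij`;
the minimum-weight Hamiltonian cycle is the shortest-assembly read
order. With binary variables `x_{i,p}` ("read `i` at tour slot `p`",
`N = n^2` in total) the layout step becomes the QUBO

    minimize  y = sum_u Q[u,u] x_u + sum_{u<v} Q[u,v] x_u x_v

where `Q` accumulates a diagonal bias `a`, a penalty `b` for two reads
in one slot, a penalty `c` for one read in two slots, and `w_ij` on
`{(i,p), (j,(p+1) mod n)}` for every slot `p` (cyclic). At a valid
permutation assignment `y = n*a + tour cost`. The exact substitution
`x = (1+s)/2` yields the equivalent Ising model `(h, J, offset)`, and
the same penalties assemble the diagonal QAOA cost Hamiltonian as a
weighted sum of `Z`/`ZZ` Pauli words.

## Worked example

Four length-10 reads are windows of the circular genome `ATGGCGTGCA`
at offsets 0, 3, 6, 9:

```r
library(quboasm)
rep <- run_pipeline(genome = "ATGGCGTGCA", offsets = c(0, 3, 6, 9), read_length = 10)
-rep$overlaps
#>        read 0 read 1 read 2 read 3
#> read 0      0     -7     -4     -1
#> read 1     -3      0     -7     -4
#> read 2     -6     -3      0     -7
#> read 3     -9     -6     -3      0
```

The 16-variable QUBO (`a = 0`, `b = c = 13`, 96 pairwise interactions)
is solved exactly over all 65,536 assignments; the four degenerate
ground states at energy −30 are the four rotations of the optimal
cycle, each stitched into a sequence:

```r
for (s in rep$solutions) cat(sprintf("tour %s: %s (%d nt, cost %g)%s\n",
  paste(s$tour, collapse = " -> "), s$sequence, s$assembled_length, s$cost,
  if (s$canonical) "  [canonical]" else ""))
#> tour 1 -> 2 -> 3 -> 0: GCGTGCAATGGCGTGCA (17 nt, cost -30)
#> tour 2 -> 3 -> 0 -> 1: TGCAATGGCGTGCAATG (17 nt, cost -30)
#> tour 3 -> 0 -> 1 -> 2: AATGGCGTGCAATGGCG (17 nt, cost -30)
#> tour 0 -> 1 -> 2 -> 3: ATGGCGTGCAATGGCGTGC (19 nt, cost -30)  [canonical]
```

The canonical 19-nt assembly is the genome plus a 9-base repeat — the
reads tile a circle, so the linear stitch keeps the closing overlap;
`circular = TRUE` trims it and returns `ATGGCGTGCA` exactly. The
stochastic solvers reach the same ground states:

```r
simulated_annealing(qubo_to_ising(tsp_to_qubo(reads_to_tsp(
  read_set(rep$reads)))), n_samples = 1000, sweeps = 1000, seed = 42)$energy[1]
#> [1] -30
run_qaoa(reads_to_tsp(read_set(rep$reads)), steps = 1, restarts = 40, seed = 7)
```

## Command line

```sh
inst/exec/quboasm pipeline --genome ATGGCGTGCA --offsets 0,3,6,9 \
    --read-length 10 --out report.json --fasta-out assembly.fasta
inst/exec/quboasm solve-sa --reads ATGGCGTGCA,GCGTGCAATG,TGCAATGGCG,AATGGCGTGC \
    --samples 1000 --sweeps 1000 --seed 42 --out samples.json
```

Subcommands: `overlap`, `encode`, `solve-exact`, `solve-sa`,
`solve-qaoa`, `assemble`, `pipeline`.

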