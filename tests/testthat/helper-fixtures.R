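# Shared fixtures, built in code.

# Small labelled record set with deterministic, perfectly separable labels:
# foldable iff the loop at position I is a -p propeller.
separable_records <- function() {
  grid <- enumerate_conformations(3, 1:2, "RH")
  grid$rmsd_nm <- ifelse(startsWith(grid$topology, "-p"), 0.05, 0.2)
  label_foldable(grid)
}

# Default-generator records on a reduced RH three-tetrad grid.
default_records <- function(loop_length_range = 1:4, helicity = "RH",
                            n_tetrads = 3, seed = 42) {
  grid <- enumerate_conformations(n_tetrads, loop_length_range, helicity)
  label_foldable(generate_records(grid, g4_sim_params(), seed = seed))
}

# Mirror of a topology: swap the sign of every signed loop.
mirror_topology <- function(topology) {
  tokens <- parse_topology(topology)
  swapped <- chartr("+-", "-+", tokens)
  format_topology(swapped)
}

# Tail probabilities of the normal truncated below at 0 (closed form),
# used as independent oracles for emission leakage and quantiles.
ptrunc0 <- function(q, mean, sd) {
  p0 <- pnorm((0 - mean) / sd)
  pmax(0, (pnorm((q - mean) / sd) - p0) / (1 - p0))
}
qtrunc0 <- function(p, mean, sd) {
  p0 <- pnorm((0 - mean) / sd)
  mean + sd * qnorm(p0 + p * (1 - p0))
}
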