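## Shared fixtures built in code.

## F3 counts of the worked-example family: 30 lines initiated, a handful lost
## before F3; of the survivors one produced balancer offspring and two had
## too few offspring, leaving the 17 recorded lines.
family140_lines <- function() {
  path <- system.file("extdata", "family140_lines.tsv", package = "mutscreen")
  read_lines_tsv(path)
}

## The same family before initial QC: the 17 recorded lines plus one line
## with balancer offspring in the F3 and two with fewer than 40 offspring.
family140_raw <- function() {
  good <- family140_lines()
  bad <- data.frame(family = 140L, line = c(4L, 7L, 8L),
                    zz = c(5L, 2L, 3L), total = c(80L, 25L, 31L),
                    balancer = c(TRUE, FALSE, FALSE))
  rbind(good, bad)
}

## Miniature enumerable trajectory and its single-interval partition.
mini_dynamics <- function(D = 6) doubling_dynamics(D)
mini_partition <- function(D = 6) interval_partition(integer(0), D)

## Division at which a two-lineage sample coalesces: the deepest division at
## which a single ancestral branch carries both samples (0 = the zygote).
coalescence_division <- function(profile) {
  A <- branch_count(profile)
  if (all(A > 1L)) 0L else max(which(A == 1L))
}

## Exact distribution of the pair-coalescence division in a complete binary
## tree of depth D: two distinct leaves have their common ancestor at depth k
## with probability 2^k * 2^(2 * (D - k - 1)) / choose(2^D, 2).
pair_coalescence_probs <- function(D) {
  k <- 0:(D - 1)
  2^k * 2^(2 * (D - k - 1)) / choose(2^D, 2)
}

## Table-6-like rates used by the synthetic generator defaults.
table6_rates <- function() c(67.371, 1.258, 0.021, 0.031, 0.177, 1.954) * 1e-3
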