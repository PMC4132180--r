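#' Germline population trajectory
#'
#' Builds the cell-population trajectory `N(0) ... N(D)` of the male germline
#' lineage used by the coalescent engine.  The trajectory has four stages:
#'
#' * cleavage (divisions 1-8): synchronous doubling, `N(i) = 2^i` up to
#'   division 7.  After the eighth division `n8` primordial germ cells (PGCs)
#'   are set aside; they are drawn from the descendants of `n5` ancestral
#'   cells at division 5 (the *sampling bias* of PGC formation).  `n5 = 32`
#'   corresponds to a uniform draw of the PGCs from all 256 cells.
#' * PGC expansion (divisions 9-14): doubling from `n8`, capped at
#'   `stem_cap`.
#' * stem-cell stage (division 15 to `D - 5`): constant pool size.
#' * spermatogenesis (last five divisions): doubling.
#'
#' @param D total number of cell divisions, between 36 and 42.
#' @param n5 number of ancestral cells at division 5 from which the PGCs
#'   descend (1-32).
#' @param n8 number of PGCs after the eighth division; must not exceed
#'   `8 * n5` (a division-5 cell has eight descendants at division 8).
#' @param stem_cap maximum size of the stem-cell pool (must be >= `n8`).
#' @return Object of class `"germline_dynamics"`: a list with the population
#'   sizes `N` (indexed `0..D` via `N[i + 1]`), per-division `stage` labels,
#'   and the backward-simulation population/parent sizes `npop`, `npar`.
#' @examples
#' dyn <- germline_dynamics(D = 38, n5 = 6, n8 = 8)
#' dyn$N[c(9, 12, 15)]  # N(8), N(11), N(14)
#' @export
germline_dynamics <- function(D = 38, n5 = 6, n8 = 8, stem_cap = 128) {
  for (nm in c("D", "n5", "n8", "stem_cap")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v != as.integer(v))
      stop("'", nm, "' must be a single integer")
  }
  D <- as.integer(D); n5 <- as.integer(n5); n8 <- as.integer(n8)
  stem_cap <- as.integer(stem_cap)
  if (D < 36L || D > 42L) stop("'D' must be between 36 and 42")
  if (n5 < 1L || n5 > 32L) stop("'n5' must be in 1..32")
  if (n8 < 1L || n8 > 256L) stop("'n8' must be in 1..256")
  if (n8 > 8L * n5)
    stop("infeasible bottleneck: n8 = ", n8, " exceeds 8 * n5 = ", 8L * n5,
         " (PGCs must descend from the n5 ancestors three divisions earlier)")
  if (stem_cap < n8) stop("'stem_cap' must be at least n8")

  N <- integer(D + 1L)
  N[1L] <- 1L
  for (i in 1:7) N[i + 1L] <- 2L^i
  N[9L] <- n8
  for (i in 9:14) N[i + 1L] <- min(n8 * 2L^(i - 8L), stem_cap)
  pool <- N[15L]
  if (D - 5L >= 15L) N[(15:(D - 5L)) + 1L] <- pool
  for (j in 1:5) N[D - 5L + j + 1L] <- pool * 2L^j

  stage <- c(rep("cleavage", 8L), rep("pgc_expansion", 6L),
             rep("stem", D - 19L), rep("spermatogenesis", 5L))

  ## Backward-pass bookkeeping: at division d the sampled lineages sit in a
  ## uniform random subset of npop[d] cells whose parents are npar[d] cells at
  ## division d - 1.  Divisions 6-8 use the restricted ancestry of the n5
  ## bottleneck ancestors; division 9's parents are the n8 PGCs.
  npop <- integer(D); npar <- integer(D)
  for (d in 1:5) { npop[d] <- 2L^d; npar[d] <- 2L^(d - 1L) }
  npop[6:8] <- n5 * c(2L, 4L, 8L); npar[6:8] <- n5 * c(1L, 2L, 4L)
  npop[9L] <- N[10L]; npar[9L] <- n8
  for (d in 10:D) { npop[d] <- N[d + 1L]; npar[d] <- N[d] }
  N <- as.integer(N); npop <- as.integer(npop); npar <- as.integer(npar)

  structure(list(type = "germline", D = D, N = N, stage = stage,
                 n5 = n5, n8 = n8, stem_cap = stem_cap,
                 npop = npop, npar = npar),
            class = "germline_dynamics")
}

#' Pure doubling dynamics (validation-scale trajectory)
#'
#' A miniature trajectory in which every cell divides at every division
#' (`N(i) = 2^i`, no bottleneck).  Small enough instances admit exhaustive
#' forward enumeration, so this is the workhorse for validating the backward
#' coalescent engine against the forward population oracle.
#'
#' @param D number of divisions (2-12; sizes beyond 2^12 cells defeat the
#'   point of an enumerable trajectory).
#' @return Object of class `"germline_dynamics"` with `type = "doubling"`.
#' @export
doubling_dynamics <- function(D) {
  if (length(D) != 1L || !is.finite(D) || D != as.integer(D) || D < 2 || D > 12)
    stop("'D' must be a single integer in 2..12")
  D <- as.integer(D)
  N <- as.integer(2^(0:D))
  structure(list(type = "doubling", D = D, N = N,
                 stage = rep("cleavage", D),
                 n5 = NA_integer_, n8 = NA_integer_, stem_cap = NA_integer_,
                 npop = as.integer(2^(1:D)), npar = as.integer(2^(0:(D - 1L)))),
            class = "germline_dynamics")
}

#' @export
print.germline_dynamics <- function(x, ...) {
  cat("Germline dynamics (", x$type, "): D = ", x$D, sep = "")
  if (x$type == "germline")
    cat(", n5 =", x$n5, ", n8 =", x$n8, ", stem pool =", x$N[15L])
  cat("\n  N(D) =", x$N[x$D + 1L], "cells;",
      sum(x$stage == "spermatogenesis"), "spermatogenesis divisions\n")
  invisible(x)
}
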