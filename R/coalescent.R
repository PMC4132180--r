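#' Simulate one sperm-sample genealogy backward through the germline
#'
#' Traces `f` sampled sperm (one per offspring line) from division `D` back to
#' division 1 through the population trajectory of `dyn`, and tabulates the
#' branch profile `B(d, s)`: the number of ancestral branches at division `d`
#' with exactly `s` sampled descendants.
#'
#' The backward step from division `d` to `d - 1` places the current lineages
#' uniformly at random (without replacement) among the `npop[d]` cells of
#' division `d`; exactly `npop[d] - npar[d]` parents have two daughter cells
#' and the rest have one, so lineages landing in sister cells coalesce.  At the
#' PGC bottleneck the lineages are confined to the descendants of the `n5`
#' division-5 ancestors; because both the PGC set and the ancestor set are
#' themselves uniform draws, the uniform-placement step remains exact.
#'
#' Uses the current R random-number generator state.
#'
#' @param f sample size (number of offspring lines), `f >= 1`.  If `f`
#'   exceeds the number of available sperm cells `N(D)`, cells are sampled
#'   with replacement and a warning is issued.
#' @param dyn a [germline_dynamics()] or [doubling_dynamics()] object.
#' @return Object of class `"branch_profile"`: integer matrix `B` of dimension
#'   `D x f` with attributes `f` and `D`.  Row `d` tabulates branch sizes at
#'   division `d`; `rowSums(B * s) == f` at every division.
#' @examples
#' set.seed(1)
#' B <- simulate_genealogy(4, doubling_dynamics(6))
#' colSums(t(B) * seq_len(4))  # == 4 at every division
#' @export
simulate_genealogy <- function(f, dyn) {
  stopifnot(inherits(dyn, "germline_dynamics"))
  if (length(f) != 1L || !is.finite(f) || f != as.integer(f) || f < 1)
    stop("'f' must be a single integer >= 1")
  f <- as.integer(f)
  D <- dyn$D
  if (f > dyn$npop[D]) {
    warning("sample size f = ", f, " exceeds N(D) = ", dyn$npop[D],
            "; sampling sperm cells with replacement")
    slots <- sample.int(dyn$npop[D], f, replace = TRUE)
    desc <- as.integer(rowsum(rep(1L, f), slots))
  } else {
    desc <- rep(1L, f)
  }
  B <- matrix(0L, nrow = D, ncol = f)
  for (d in D:1) {
    B[d, ] <- tabulate(desc, nbins = f)
    if (d > 1L) {
      A <- length(desc)
      ndiv <- dyn$npop[d] - dyn$npar[d]
      slots <- sample.int(dyn$npop[d], A)
      par <- ifelse(slots <= 2L * ndiv, (slots + 1L) %/% 2L, slots - ndiv)
      desc <- as.integer(rowsum(desc, par))
    }
  }
  structure(B, f = f, D = D, class = "branch_profile")
}

#' Ancestral branch counts A(d) of a branch profile
#'
#' @param profile a `"branch_profile"` matrix from [simulate_genealogy()].
#' @return Integer vector of length `D`: the number of distinct ancestral
#'   branches at each division (non-increasing backward in time).
#' @export
branch_count <- function(profile) {
  as.integer(rowSums(unclass(profile)))
}

#' Monte-Carlo set of branch-profile coefficients
#'
#' Simulates `M` independent genealogies for sample size `f` under dynamics
#' `dyn` and stores their branch profiles.  These are the coefficients that
#' enter the mutation-pattern likelihood.
#'
#' @inheritParams simulate_genealogy
#' @param M number of replicate genealogies, `M >= 1`.
#' @param seed integer seed; the simulation is reproducible given `(f, dyn,
#'   M, seed)`.  `NULL` uses (and advances) the current RNG state.
#' @return Object of class `"coal_coefficients"`: list with `f`, `D`, `M`,
#'   the integer array `B` of dimension `D x f x M`, the dynamics descriptor
#'   and the seed.
#' @export
simulate_coefficients <- function(f, dyn, M, seed = NULL) {
  stopifnot(inherits(dyn, "germline_dynamics"))
  if (length(M) != 1L || !is.finite(M) || M < 1) stop("'M' must be >= 1")
  M <- as.integer(M)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  f <- as.integer(f)
  B <- array(0L, dim = c(dyn$D, f, M))
  for (m in seq_len(M)) B[, , m] <- simulate_genealogy(f, dyn)
  structure(list(f = f, D = dyn$D, M = M, B = B,
                 dynamics = dyn[c("type", "D", "n5", "n8", "stem_cap")],
                 seed = seed),
            class = "coal_coefficients")
}

#' @export
print.coal_coefficients <- function(x, ...) {
  cat("Coalescent coefficient set: f =", x$f, ", D =", x$D, ", M =", x$M, "\n")
  invisible(x)
}

#' Pool coefficient sets simulated under different dynamics
#'
#' Grouped germline-dynamics values (for example `n5` in 5-6 with `n8` in 7-9)
#' are represented by pooling equal-size coefficient sets simulated at each
#' integer combination in the group; the pattern likelihood then averages over
#' the pooled genealogies.
#'
#' @param sets list of `"coal_coefficients"` objects sharing `f` and `D`.
#' @return A single pooled `"coal_coefficients"` object with
#'   `M = sum(M_j)`.
#' @export
pool_coefficients <- function(sets) {
  if (inherits(sets, "coal_coefficients")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, TRUE, "coal_coefficients")))
  f <- sets[[1L]]$f; D <- sets[[1L]]$D
  for (s in sets) {
    if (s$f != f) stop("cannot pool coefficient sets with different f")
    if (s$D != D) stop("cannot pool coefficient sets with different D")
  }
  M <- sum(vapply(sets, `[[`, 1L, "M"))
  B <- array(unlist(lapply(sets, `[[`, "B"), use.names = FALSE),
             dim = c(D, f, M))
  structure(list(f = f, D = D, M = M, B = B,
                 dynamics = lapply(sets, `[[`, "dynamics"),
                 seed = lapply(sets, `[[`, "seed")),
            class = "coal_coefficients")
}

#' Forward whole-population oracle
#'
#' Brute-force validation counterpart of [simulate_genealogy()]: simulates
#' every cell of the germline population forward in time with explicit parent
#' pointers, samples `f` sperm uniformly without replacement from the `N(D)`
#' final cells, and tabulates the same branch-profile statistics by walking
#' the parent pointers.  Only feasible for trajectories with `N(D) <= 4096`.
#'
#' @inheritParams simulate_genealogy
#' @return A `"branch_profile"` matrix, as from [simulate_genealogy()].
#' @export
forward_population_oracle <- function(dyn, f) {
  stopifnot(inherits(dyn, "germline_dynamics"))
  D <- dyn$D
  ND <- dyn$N[D + 1L]
  if (ND > 4096) stop("population too large to enumerate (N(D) = ", ND, ")")
  f <- as.integer(f)
  if (f < 1L || f > ND) stop("'f' must be in 1..N(D) for the forward oracle")

  if (dyn$type == "doubling") {
    ## Complete binary tree: cell j at division d has parent ceiling(j / 2).
    anc <- sample.int(ND, f)                # leaves at division D
    B <- matrix(0L, D, f)
    for (d in D:1) {
      B[d, ] <- tabulate(tabulate(anc, nbins = 2L^d), nbins = f)
      anc <- (anc + 1L) %/% 2L
    }
    return(structure(B, f = f, D = D, class = "branch_profile"))
  }

  n5 <- dyn$n5; n8 <- dyn$n8
  ## Divisions 1..8: full embryonic doubling tree (256 cells), complete-tree
  ## parent arithmetic.  Bottleneck: n5 ancestors uniform among the 32 cells
  ## at division 5; PGCs uniform among their 8 * n5 descendants at division 8.
  anc5 <- sample.int(32L, n5)
  desc8 <- as.vector(outer(0:7, (anc5 - 1L) * 8L, `+`)) + 1L  # division-8 ids
  pgc <- sample(desc8, n8)
  ## Divisions 9..D: population grown from the PGCs; at each division a
  ## uniform subset of parents divides.  par[[d]] maps division-d cells to
  ## division-(d-1) cells (germline indexing; division 8 cells are the PGCs).
  par <- vector("list", D)
  for (d in 9:D) {
    n_prev <- dyn$N[d]; n_cur <- dyn$N[d + 1L]
    extra <- if (n_cur > n_prev) sample.int(n_prev, n_cur - n_prev) else integer(0)
    par[[d]] <- c(seq_len(n_prev), extra)
  }
  leaves <- sample.int(ND, f)
  B <- matrix(0L, D, f)
  anc <- leaves
  for (d in D:9) {
    B[d, ] <- tabulate(tabulate(anc, nbins = dyn$N[d + 1L]), nbins = f)
    anc <- par[[d]][anc]
  }
  anc <- pgc[anc]                           # full-tree division-8 cell ids
  for (d in 8:1) {
    B[d, ] <- tabulate(tabulate(anc, nbins = 2L^d), nbins = f)
    anc <- (anc + 1L) %/% 2L
  }
  structure(B, f = f, D = D, class = "branch_profile")
}
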