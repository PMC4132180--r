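## Mutation-pattern likelihood.
##
## Conditional on a genealogy G of f sampled sperm, mutations of size s arise
## as a Poisson count with mean lambda_s(G, u) = sum_d u_{I(d)} B_G(d, s):
## each ancestral branch at division d that has s sampled descendants
## contributes an independent chance u_{I(d)} of a mutation carried by exactly
## those s lines.  The pattern probability p_f(kappa) averages the product of
## Poisson terms over M simulated genealogies.

.logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

.slab <- function(Cs, s) {
  ## M x I slice of the M x I x f coefficient array, dims preserved.
  matrix(Cs[, , s], nrow = dim(Cs)[1L], ncol = dim(Cs)[2L])
}

#' Collapse coalescent coefficients onto a division-interval partition
#'
#' Aggregates the per-division branch profiles of a coefficient set over the
#' intervals of `partition`, the form consumed by the pattern likelihood.
#'
#' @param coeffs a `"coal_coefficients"` set from [simulate_coefficients()].
#' @param partition an [interval_partition()] with the same `D`.
#' @return Object of class `"pattern_coeffs"`: list with `f`, `M`, `I`, the
#'   array `Cs` (`M x I x f`; `Cs[m, i, s]` is the number of
#'   branch-divisions in interval `i` with `s` descendants in genealogy `m`)
#'   and the matrix `S` (`M x I`; total branch-divisions per interval).
#' @export
pattern_coefficients <- function(coeffs, partition) {
  stopifnot(inherits(coeffs, "coal_coefficients"),
            inherits(partition, "interval_partition"))
  if (coeffs$D != partition$D)
    stop("coefficient set has D = ", coeffs$D, " but partition has D = ",
         partition$D)
  D <- coeffs$D; f <- coeffs$f; M <- coeffs$M; I <- partition$I
  idx <- division_interval_map(partition)
  Bm <- matrix(coeffs$B, nrow = D)                  # D x (f*M)
  C <- rowsum(Bm, idx)                              # I x (f*M)
  Cs <- aperm(array(C, c(I, f, M)), c(3L, 1L, 2L))  # M x I x f
  S <- t(apply(array(C, c(I, f, M)), c(1L, 3L), sum))  # M x I
  Cmat <- matrix(aperm(array(C, c(I, f, M)), c(3L, 2L, 1L)), nrow = M * f)
  structure(list(f = f, M = M, I = I, Cs = Cs, S = S, Cmat = Cmat,
                 partition = partition),
            class = "pattern_coeffs")
}

#' Log-probability of a mutation pattern
#'
#' @param sizes integer vector: the mutation pattern (multiset of mutation
#'   sizes; empty vector for a non-mutant family).
#' @param f family size.
#' @param u per-interval mutation rates (a [rate_vector()] or bare numeric of
#'   length `I`).
#' @param coeffs a `"pattern_coeffs"` object from [pattern_coefficients()]
#'   with matching `f`.
#' @return Log of the pattern probability, in `[-Inf, 0]`.  Patterns whose
#'   sizes sum beyond `f` violate the one-mutation-per-line constraint and get
#'   probability zero (with a warning).
#' @examples
#' dyn <- doubling_dynamics(6)
#' pc <- pattern_coefficients(simulate_coefficients(3, dyn, 200, seed = 1),
#'                            interval_partition(integer(0), 6))
#' pattern_log_prob(integer(0), 3, 0.01, pc)
#' @export
pattern_log_prob <- function(sizes, f, u, coeffs) {
  stopifnot(inherits(coeffs, "pattern_coeffs"))
  if (coeffs$f != f) stop("coefficient set was simulated for f = ", coeffs$f)
  sizes <- as.integer(sizes)
  if (sum(sizes) > f) {
    warning("pattern sizes sum to ", sum(sizes), " > family size ", f,
            "; probability 0")
    return(-Inf)
  }
  u <- .rates(u, coeffs$partition)
  g <- as.vector(-(coeffs$S %*% u))
  if (length(sizes)) {
    tb <- table(sizes)
    for (j in seq_along(tb)) {
      s <- as.integer(names(tb))[j]; m <- as.integer(tb[[j]])
      lam <- as.vector(.slab(coeffs$Cs, s) %*% u)
      g <- g + m * log(lam) - lfactorial(m)
    }
  }
  .logmeanexp(g)
}

## Shared evaluator: log-likelihood of a tally and (optionally) its gradient
## with respect to the interval rates u.  coeffs: named list of
## "pattern_coeffs" keyed by family size.
.tally_ll <- function(tally, u, coeffs, grad = FALSE) {
  e <- tally$entries
  I <- length(u)
  total <- 0
  gtot <- if (grad) numeric(I) else NULL
  for (fs in names(tally$families)) {
    pc <- coeffs[[fs]]
    f <- as.integer(fs)
    M <- pc$M
    nfam <- tally$families[[fs]]
    rows <- which(e$f == f)
    nonempty <- if (length(rows)) sum(e$n[rows]) else 0L
    pats <- c(lapply(e$key[rows], .key_sizes), list(integer(0)))
    ns <- c(e$n[rows], nfam - nonempty)
    base_g <- as.vector(-(pc$S %*% u))
    lam_all <- matrix(pc$Cmat %*% u, nrow = M)        # M x f, by size s
    log_lam <- log(lam_all)
    for (p in seq_along(pats)) {
      n <- ns[p]
      if (n == 0L) next
      sizes <- pats[[p]]
      g <- base_g
      m_list <- integer(0); s_list <- integer(0)
      if (length(sizes)) {
        tb <- tabulate(sizes, nbins = f)
        s_list <- which(tb > 0L); m_list <- tb[s_list]
        for (j in seq_along(s_list))
          g <- g + m_list[j] * log_lam[, s_list[j]] - lfactorial(m_list[j])
      }
      lp <- .logmeanexp(g)
      if (!is.finite(lp)) return(list(value = -Inf, grad = NULL))
      total <- total + n * lp
      if (grad) {
        w <- exp(g - max(g)); w <- w / sum(w)
        gpat <- -as.vector(crossprod(w, pc$S))
        for (j in seq_along(s_list)) {
          lam <- lam_all[, s_list[j]]
          wl <- ifelse(lam > 0, w * (m_list[j] / lam), 0)
          gpat <- gpat + as.vector(crossprod(wl, .slab(pc$Cs, s_list[j])))
        }
        gtot <- gtot + n * gpat
      }
    }
  }
  list(value = total, grad = gtot)
}

#' Log-likelihood of a pattern tally
#'
#' Experiment-wide log-likelihood: families are independent, so the
#' log-likelihood is the sum over family sizes and patterns of
#' `n_f(kappa) * log p_f(kappa)`, with explicit empty-pattern terms for the
#' non-mutant families.
#'
#' @param tally a [pattern_tally()].
#' @param u per-interval mutation rates (numeric or [rate_vector()]).
#' @param coeffs named list of `"pattern_coeffs"` objects keyed by family
#'   size (as character), covering every size present in the tally.
#' @return The log-likelihood (scalar; `-Inf` if some observed pattern has
#'   zero probability).
#' @export
tally_log_likelihood <- function(tally, u, coeffs) {
  stopifnot(inherits(tally, "pattern_tally"))
  need <- names(tally$families)
  missing <- setdiff(need, names(coeffs))
  if (length(missing))
    stop("no coefficient set for family size(s): ",
         paste(missing, collapse = ", "))
  I <- coeffs[[need[1L]]]$I
  u <- .rates(u, coeffs[[need[1L]]]$partition)
  .tally_ll(tally, u, coeffs, grad = FALSE)$value
}

#' Simulate and collapse coefficient sets for every family size of a tally
#'
#' Convenience wrapper: one coefficient set per family size present in the
#' tally, all under the same dynamics and partition.
#'
#' @inheritParams tally_log_likelihood
#' @param dyn a [germline_dynamics()] object.
#' @param partition an [interval_partition()].
#' @param M replicates per family size.
#' @param seed integer seed (offset deterministically per family size).
#' @return Named list of `"pattern_coeffs"` keyed by family size.
#' @export
tally_coefficients <- function(tally, dyn, partition, M = 1000, seed = 1) {
  sizes <- tally_sizes(tally)
  out <- list()
  for (k in seq_along(sizes)) {
    cs <- simulate_coefficients(sizes[k], dyn, M, seed = seed + k - 1L)
    out[[as.character(sizes[k])]] <- pattern_coefficients(cs, partition)
  }
  out
}
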