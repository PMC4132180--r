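## Maximum-likelihood estimation of interval rates, nested hypothesis tests,
## and the germline-dynamics grid scan.

#' Hypothesis on the interval rates
#'
#' Standard nested hypotheses about the per-interval rates, expressed as
#' equality classes over the interval indices `1..I`:
#'
#' * `H1`: all rates equal.
#' * `H2`: all rates except the first and last equal.
#' * `H3`: `u1 = u2`. `H4`: `u2 = u3`. `H4b`: `u3 = u4`.
#' * `H5`: `u[I-2] = u[I-1]`. `H6`: `u[I-1] = u[I]`. `H7`: `u1 = uI`.
#' * `H8`: no restriction.
#'
#' @param id one of `"H1"`, `"H2"`, `"H3"`, `"H4"`, `"H4b"`, `"H5"`, `"H6"`,
#'   `"H7"`, `"H8"`.
#' @param I number of intervals.
#' @return Object of class `"hypothesis_spec"`: list with `id`, `classes`
#'   (integer vector mapping interval to parameter class) and `df` (degrees
#'   of freedom of the likelihood-ratio test against `H8`, computed
#'   structurally as `I - number of classes`).
#' @export
hypothesis_spec <- function(id, I) {
  I <- as.integer(I)
  if (I < 2L && id != "H8") stop("constrained hypotheses require at least 2 intervals")
  classes <- seq_len(I)
  merge <- function(cl, a, b) { cl[cl == cl[b]] <- cl[a]; cl }
  switch(id,
    H1 = classes <- rep(1L, I),
    H2 = { if (I >= 4L) classes[2:(I - 1L)] <- 2L },
    H3 = classes <- merge(classes, 1L, 2L),
    H4 = { if (I >= 3L) classes <- merge(classes, 2L, 3L) else stop("H4 needs I >= 3") },
    H4b = { if (I >= 4L) classes <- merge(classes, 3L, 4L) else stop("H4b needs I >= 4") },
    H5 = { if (I >= 3L) classes <- merge(classes, I - 2L, I - 1L) else stop("H5 needs I >= 3") },
    H6 = classes <- merge(classes, I - 1L, I),
    H7 = classes <- merge(classes, 1L, I),
    H8 = NULL,
    stop("unknown hypothesis id: ", id)
  )
  classes <- match(classes, unique(classes))
  structure(list(id = id, I = I, classes = classes,
                 df = I - length(unique(classes))),
            class = "hypothesis_spec")
}

#' Equality-class hypothesis from an explicit class vector
#'
#' @param classes integer vector of length `I` assigning each interval to a
#'   shared-rate class.
#' @param id label for the constraint set.
#' @return A `"hypothesis_spec"` object.
#' @export
hypothesis_classes <- function(classes, id = "custom") {
  classes <- match(classes, unique(classes))
  structure(list(id = id, I = length(classes), classes = classes,
                 df = length(classes) - length(unique(classes))),
            class = "hypothesis_spec")
}

.LOG_FLOOR <- log(1e-12)

## Deterministic spread of optimizer starting points.  The likelihood is
## bimodal between the first-interval rate and the next ones (very large
## clusters fit either), so a first-class-dominant start is always included.
.start_grid <- function(K, n_starts) {
  starts <- list(rep(1e-3, K),
                 c(5e-2, rep(1e-4, max(K - 1L, 0L))),
                 rep(1e-2, K),
                 rep(1e-4, K))
  mags <- c(1e-3, 1e-2, 1e-4, 1e-1, 1e-5, 3e-3, 3e-2, 3e-4)
  k <- length(starts)
  while (k < n_starts) {
    k <- k + 1L
    starts[[k]] <- mags[((seq_len(K) + k - 2L) %% length(mags)) + 1L]
  }
  starts[seq_len(max(n_starts, 2L))]
}

#' Maximum-likelihood estimation of interval mutation rates
#'
#' Maximizes the pattern-tally log-likelihood over the per-interval rates,
#' optionally under an equality-class constraint ([hypothesis_spec()]).  The
#' optimization is box-constrained quasi-Newton (`L-BFGS-B`) on
#' log-transformed rates with an analytic gradient and multiple deterministic
#' starting points; rates that slam the lower floor (`1e-12`) are snapped to
#' zero for reporting.
#'
#' @inheritParams tally_log_likelihood
#' @param hypothesis a `"hypothesis_spec"` constraint, or `NULL` for the
#'   unconstrained fit (`H8`).
#' @param n_starts number of optimizer starts (default 8).
#' @param extra_starts optional list of rate vectors used as additional
#'   starting points.
#' @param upper upper bound for any per-division rate.
#' @return Object of class `"rate_fit"`: list with `u` (estimated rates,
#'   length `I`), `u_raw` (before zero-snapping), `loglik`, `hypothesis`,
#'   `partition`, `converged`, `n_starts`, `n_params`.
#' @export
fit_mle <- function(tally, coeffs, hypothesis = NULL, n_starts = 8,
                    extra_starts = NULL, upper = 0.8) {
  stopifnot(inherits(tally, "pattern_tally"))
  need <- names(tally$families)
  missing <- setdiff(need, names(coeffs))
  if (length(missing))
    stop("no coefficient set for family size(s): ",
         paste(missing, collapse = ", "))
  partition <- coeffs[[need[1L]]]$partition
  I <- partition$I
  if (is.null(hypothesis)) hypothesis <- hypothesis_spec("H8", I)
  stopifnot(inherits(hypothesis, "hypothesis_spec"), hypothesis$I == I)
  cls <- hypothesis$classes
  K <- length(unique(cls))

  ## All-empty tally: likelihood is maximized by u = 0 exactly.
  if (nrow(tally$entries) == 0L) {
    return(structure(list(u = numeric(I), u_raw = numeric(I), loglik = 0,
                          hypothesis = hypothesis, partition = partition,
                          converged = TRUE, n_starts = 0L, n_params = K),
                     class = "rate_fit"))
  }

  cache <- new.env(parent = emptyenv())
  eval_theta <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    u <- exp(theta)[cls]
    r <- .tally_ll(tally, u, coeffs, grad = TRUE)
    if (!is.finite(r$value)) {
      r <- list(value = -1e12, grad = numeric(I))
    }
    gk <- vapply(seq_len(K), function(k) sum(r$grad[cls == k] * u[cls == k]),
                 numeric(1))
    cache$key <- key; cache$val <- list(value = r$value, gtheta = gk)
    cache$val
  }
  fn <- function(theta) -eval_theta(theta)$value
  gr <- function(theta) -eval_theta(theta)$gtheta

  starts <- .start_grid(K, n_starts)
  for (es in extra_starts) {
    u0 <- pmax(.rates(es, partition), 1e-12)
    starts[[length(starts) + 1L]] <-
      vapply(seq_len(K), function(k) mean(u0[cls == k]), numeric(1))
  }
  best <- NULL
  convs <- integer(0)
  for (u0 in starts) {
    th0 <- pmin(pmax(log(u0), .LOG_FLOOR), log(upper))
    opt <- tryCatch(
      stats::optim(th0, fn, gr, method = "L-BFGS-B",
                   lower = .LOG_FLOOR, upper = log(upper),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt)) next
    convs <- c(convs, opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimizer failed from every starting point")
  u_raw <- exp(best$par)[cls]
  u <- ifelse(u_raw <= 1e-10, 0, u_raw)
  structure(list(u = u, u_raw = u_raw, loglik = -best$value,
                 hypothesis = hypothesis, partition = partition,
                 converged = any(convs == 0L), n_starts = length(starts),
                 n_params = K),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Rate fit (", x$hypothesis$id, "): logL = ",
      formatC(x$loglik, format = "f", digits = 2), "\n  u x 10^3: ",
      paste(formatC(x$u * 1e3, format = "f", digits = 3), collapse = " "),
      if (!x$converged) "\n  WARNING: optimizer did not report convergence",
      "\n", sep = "")
  invisible(x)
}

#' Overall mutation rate from interval rates
#'
#' The overall rate per generation is the sum of the per-division rates over
#' all divisions, i.e. the width-weighted sum of the interval rates.
#'
#' @param u interval rates ([rate_vector()] or numeric of length `I`).
#' @param partition an [interval_partition()] (ignored when `u` is a
#'   `rate_vector`, which carries its own).
#' @return The overall mutation rate per generation.
#' @examples
#' p <- interval_partition(c(1, 2, 3, 14, -5), 38)
#' overall_rate(c(67.371, 1.258, 0.021, 0.031, 0.177, 1.954) * 1e-3, p)
#' @export
overall_rate <- function(u, partition = NULL) {
  if (inherits(u, "rate_vector")) partition <- u$partition
  stopifnot(inherits(partition, "interval_partition"))
  sum(partition$widths * .rates(u, partition))
}

#' Classical overall mutation-rate estimator
#'
#' The assumption-free estimator: number of mutant lines divided by the total
#' number of lines screened.
#'
#' @param n_mutants number of mutant lines.
#' @param n_lines total number of lines screened (positive).
#' @return The rate estimate (unrounded).
#' @examples
#' round(classical_rate(2673, 271794), 4)
#' @export
classical_rate <- function(n_mutants, n_lines) {
  if (n_lines <= 0) stop("'n_lines' must be positive")
  if (n_mutants < 0 || n_mutants > n_lines)
    stop("'n_mutants' must be between 0 and 'n_lines'")
  n_mutants / n_lines
}

#' Likelihood-ratio test of a rate hypothesis
#'
#' Tests a constrained hypothesis `Hi` against the unconstrained model `H8`
#' using `2 * (lnL_H8 - lnL_Hi)`, asymptotically chi-square with structural
#' degrees of freedom (difference in free-parameter counts).  Solutions are
#' cross-seeded between the two fits so the statistic cannot go negative
#' beyond optimizer tolerance.
#'
#' @inheritParams fit_mle
#' @param hypothesis the constrained [hypothesis_spec()] (`H1`-`H7` or a
#'   custom equality-class constraint).
#' @param fit_h8 optional pre-computed unconstrained fit to reuse.
#' @return List with `statistic`, `df`, `p_value`, `fit_h8`, `fit_h`.
#' @export
lr_test <- function(tally, coeffs, hypothesis, n_starts = 8, fit_h8 = NULL) {
  stopifnot(inherits(hypothesis, "hypothesis_spec"))
  if (hypothesis$df < 1L) stop("the constrained hypothesis must remove at least one parameter")
  if (is.null(fit_h8))
    fit_h8 <- fit_mle(tally, coeffs, hypothesis = NULL, n_starts = n_starts)
  fit_h <- fit_mle(tally, coeffs, hypothesis = hypothesis,
                   n_starts = n_starts, extra_starts = list(fit_h8$u_raw))
  ## If the constrained fit beats the free fit, the free fit missed the
  ## optimum: refit seeding with the constrained solution.
  if (fit_h$loglik > fit_h8$loglik) {
    fit_h8 <- fit_mle(tally, coeffs, hypothesis = NULL,
                      n_starts = n_starts, extra_starts = list(fit_h$u_raw))
  }
  stat <- 2 * (fit_h8$loglik - fit_h$loglik)
  if (stat < -1e-3)
    stop("negative likelihood-ratio statistic beyond tolerance (", stat, ")")
  stat <- max(stat, 0)
  df <- hypothesis$df
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       fit_h8 = fit_h8, fit_h = fit_h)
}

#' Grid scan over germline-dynamics assumptions
#'
#' Maximizes the likelihood on a grid of `(n5, n8)` groups (and optionally a
#' fixed `D`), reporting for each feasible cell the maximized log-likelihood
#' and its drop `delta` from the best cell.  A group of integers (for example
#' `n5` in `5:6` with `n8` in `7:9`) is represented by pooling equal-size
#' coefficient sets simulated at each feasible integer combination.
#'
#' @inheritParams fit_mle
#' @param partition an [interval_partition()].
#' @param n5_groups,n8_groups lists of integer vectors (the grid groups).
#' @param D total divisions for every cell.
#' @param stem_cap stem-cell pool cap passed to [germline_dynamics()].
#' @param M total coalescent replicates per cell and family size (split
#'   evenly across the feasible integer combinations of the cell).
#' @param seed integer seed; per-cell seeds are derived deterministically.
#' @param cache optional precomputed per-cell coefficient cache from
#'   [scan_coefficients()]; reuse it when scanning several tallies over the
#'   same grid.
#' @return Data frame with one row per cell: `n5_group`, `n8_group`,
#'   `feasible` (any feasible combination), `partial` (some combinations
#'   infeasible), `loglik`, `delta`.  The optimum row has `delta == 0`.
#' @export
scan_dynamics <- function(tally, partition, n5_groups, n8_groups, D = 38,
                          stem_cap = 128, M = 500, seed = 1, n_starts = 4,
                          cache = NULL) {
  stopifnot(inherits(tally, "pattern_tally"))
  if (is.null(cache))
    cache <- scan_coefficients(tally_sizes(tally), partition, n5_groups,
                               n8_groups, D = D, stem_cap = stem_cap,
                               M = M, seed = seed)
  rows <- list()
  warm <- NULL
  for (cell in seq_along(cache)) {
    info <- cache[[cell]]
    row <- data.frame(n5_group = info$n5_group, n8_group = info$n8_group,
                      feasible = info$feasible, partial = info$partial,
                      loglik = NA_real_, stringsAsFactors = FALSE)
    if (info$feasible) {
      fit <- fit_mle(tally, info$coeffs, n_starts = n_starts,
                     extra_starts = warm)
      row$loglik <- fit$loglik
      warm <- list(fit$u_raw)
    }
    rows[[cell]] <- row
  }
  out <- do.call(rbind, rows)
  best <- max(out$loglik, na.rm = TRUE)
  out$delta <- best - out$loglik
  out
}

#' Precompute pooled coefficient sets for a dynamics grid
#'
#' @param sizes family sizes the coefficients must cover.
#' @inheritParams scan_dynamics
#' @return List with one element per grid cell: group labels, feasibility
#'   flags, and the pooled collapsed coefficient sets keyed by family size.
#' @export
scan_coefficients <- function(sizes, partition, n5_groups, n8_groups,
                              D = 38, stem_cap = 128, M = 500, seed = 1) {
  lab <- function(g) if (length(g) > 1L) paste0(min(g), "-", max(g)) else as.character(g)
  sizes <- sort(unique(as.integer(sizes)))
  out <- list()
  cell <- 0L
  for (i5 in seq_along(n5_groups)) for (i8 in seq_along(n8_groups)) {
    cell <- cell + 1L
    g5 <- as.integer(n5_groups[[i5]]); g8 <- as.integer(n8_groups[[i8]])
    combos <- expand.grid(n5 = g5, n8 = g8)
    ok <- combos$n8 <= 8L * combos$n5 & combos$n5 <= 32L & combos$n8 <= 256L
    info <- list(n5_group = lab(g5), n8_group = lab(g8),
                 feasible = any(ok), partial = any(ok) && any(!ok),
                 coeffs = NULL)
    if (any(ok)) {
      combos <- combos[ok, , drop = FALSE]
      Mper <- max(1L, ceiling(M / nrow(combos)))
      coeffs <- list()
      for (k in seq_along(sizes)) {
        sets <- vector("list", nrow(combos))
        for (j in seq_len(nrow(combos))) {
          dyn <- germline_dynamics(D, combos$n5[j], combos$n8[j],
                                   stem_cap = max(stem_cap, combos$n8[j]))
          ## same seed for the j-th combo in every cell: common random
          ## numbers couple the genealogies across cells (they share the
          ## trajectory outside the bottleneck divisions), so likelihood
          ## differences between cells are not swamped by Monte-Carlo noise
          sets[[j]] <- simulate_coefficients(
            sizes[k], dyn, Mper,
            seed = seed + 1009L * k + j)
        }
        coeffs[[as.character(sizes[k])]] <-
          pattern_coefficients(pool_coefficients(sets), partition)
      }
      info$coeffs <- coeffs
    }
    out[[cell]] <- info
  }
  out
}

#' Ratio of the first-division rate to the mean internal-division rate
#'
#' Computed from a six-interval rate vector as
#' `u1 / ((u2 + u3 + 11 * u4 + 18 * u5) / 32)`: the denominator averages the
#' rates of the internal divisions (second division through the stem-cell
#' stage) as reported alongside the rate tables.
#'
#' @param u interval rates, at least 5 elements.
#' @return The ratio (0 if `u1 = 0`; `Inf` if the denominator vanishes while
#'   `u1 > 0`; `NaN` if both vanish).
#' @export
first_division_ratio <- function(u) {
  if (inherits(u, "rate_vector")) u <- u$u
  if (length(u) < 5L) stop("needs at least 5 interval rates")
  denom <- (u[2] + u[3] + 11 * u[4] + 18 * u[5]) / 32
  if (denom == 0) {
    if (u[1] == 0) return(NaN)
    return(Inf)
  }
  u[1] / denom
}

#' Expected male-to-female mutation-rate ratio
#'
#' If the first division mutates at `r` times the rate of every other
#' division, a germline with `male_divisions` cell divisions accumulates
#' `r + male_divisions - 1` division-equivalents of mutation, and likewise
#' for the female germline; their quotient is the expected male:female
#' per-generation rate ratio.
#'
#' @param r ratio of the first-division rate to the common rate of the other
#'   divisions.
#' @param male_divisions,female_divisions numbers of germline cell divisions
#'   (defaults 400 and 30, the usual figures for 30-year-old humans).
#' @return The expected ratio.
#' @examples
#' round(male_female_ratio(100), 1)  # 3.9
#' @export
male_female_ratio <- function(r, male_divisions = 400, female_divisions = 30) {
  stopifnot(r > 0, male_divisions > 0, female_divisions > 0)
  (r + male_divisions - 1) / (r + female_divisions - 1)
}
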