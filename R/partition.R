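#' Division-interval partition of germline development
#'
#' Germline development from the zygote to sperm is modelled as `D` consecutive
#' cell divisions, grouped into `I` intervals `[t[i-1]+1, t[i]]` within which
#' the mutation rate per cell division is assumed constant.  A partition is
#' specified by its interior boundaries `t[1] < ... < t[I-1]`; the final
#' boundary is always `D`.
#'
#' Negative shorthand: because the exact number of divisions varies between
#' sperm while the last five divisions are always spermatogenesis, a negative
#' entry `-k` resolves to the boundary `D - k`, i.e. it makes the following
#' interval cover the final `k` divisions.  So `c(1, 2, 14, -5)` with `D = 38`
#' yields intervals `[1,1], [2,2], [3,14], [15,33], [34,38]`.
#'
#' @param spec integer vector of interior boundaries, possibly negative
#'   (see Details).  An empty spec gives a single interval `[1, D]`.
#' @param D total number of cell divisions (at least 6).
#' @return An object of class `"interval_partition"`: a list with elements
#'   `boundaries` (`t[0] = 0, ..., t[I] = D`), `D`, `I` and `widths`.
#' @examples
#' interval_partition(c(1, 2, 14, -5), D = 38)
#' interval_partition(integer(0), D = 36)
#' @export
interval_partition <- function(spec = integer(0), D) {
  if (length(D) != 1L || !is.finite(D) || D != as.integer(D) || D < 6)
    stop("'D' must be a single integer >= 6")
  D <- as.integer(D)
  spec <- as.integer(spec)
  if (any(spec == 0L))
    stop("partition boundary entry ", which(spec == 0L)[1L], " is zero")
  resolved <- ifelse(spec < 0L, D + spec, spec)
  bad <- which(resolved <= 0L | resolved >= D)
  if (length(bad))
    stop("partition boundary ", spec[bad[1L]], " resolves to ", resolved[bad[1L]],
         ", outside 1..", D - 1L)
  if (length(resolved) > 1L && any(diff(resolved) <= 0L)) {
    i <- which(diff(resolved) <= 0L)[1L] + 1L
    stop("partition boundary ", spec[i], " (resolved ", resolved[i],
         ") does not increase on the previous boundary")
  }
  t <- c(0L, resolved, D)
  structure(list(boundaries = t, D = D, I = length(t) - 1L, widths = diff(t)),
            class = "interval_partition")
}

#' @export
print.interval_partition <- function(x, ...) {
  iv <- paste0("[", x$boundaries[-length(x$boundaries)] + 1L, ",",
               x$boundaries[-1L], "]")
  cat("Division-interval partition: D =", x$D, ", I =", x$I, "\n ",
      paste(iv, collapse = " "), "\n")
  invisible(x)
}

#' Map each cell division to its interval index
#'
#' @param partition an [interval_partition()].
#' @return Integer vector of length `D`; element `d` is the interval index of
#'   division `d`.
#' @examples
#' division_interval_map(interval_partition(c(1, 2, 14, -5), 38))
#' @export
division_interval_map <- function(partition) {
  stopifnot(inherits(partition, "interval_partition"))
  rep.int(seq_len(partition$I), partition$widths)
}

#' Per-interval mutation rates
#'
#' Bundles a vector of per-cell-division mutation rates (one per interval,
#' dimensionless probabilities) with the partition that defines the intervals.
#'
#' @param u numeric vector of non-negative rates, length `partition$I`.
#' @param partition an [interval_partition()].
#' @return Object of class `"rate_vector"`.
#' @export
rate_vector <- function(u, partition) {
  stopifnot(inherits(partition, "interval_partition"))
  u <- as.numeric(u)
  if (length(u) != partition$I)
    stop("'u' has length ", length(u), " but the partition has ",
         partition$I, " intervals")
  if (any(!is.finite(u)) || any(u < 0))
    stop("mutation rates must be finite and non-negative")
  structure(list(u = u, partition = partition), class = "rate_vector")
}

#' @export
print.rate_vector <- function(x, ...) {
  cat("Per-interval mutation rates (x 10^3):",
      paste(formatC(x$u * 1e3, format = "f", digits = 3), collapse = " "), "\n")
  invisible(x)
}

## Accept either a rate_vector or a bare numeric of the right length.
.rates <- function(u, partition) {
  if (inherits(u, "rate_vector")) {
    if (!identical(u$partition$boundaries, partition$boundaries))
      stop("rate vector was built for a different partition")
    u$u
  } else {
    if (length(u) != partition$I)
      stop("rate vector length ", length(u), " != interval count ", partition$I)
    as.numeric(u)
  }
}
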