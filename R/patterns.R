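## Mutation patterns and pattern tallies.
##
## A mutation pattern is the multiset of "mutation sizes" in one family: each
## independent mutation contributes the number of offspring lines that carry
## it.  A tally aggregates patterns over families of each size f, counting
## occurrences n_f(kappa); non-mutant families carry the empty pattern.

.canon_sizes <- function(sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("mutation sizes must be positive integers")
  sort(sizes)
}

.sizes_key <- function(sizes) paste(.canon_sizes(sizes), collapse = ",")

.key_sizes <- function(key) {
  if (!nzchar(key)) integer(0) else as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
}

#' Build a pattern tally from per-family patterns
#'
#' @param f integer vector of family sizes, one entry per family.
#' @param patterns list of integer vectors, one per family; each vector is the
#'   multiset of mutation sizes observed in that family (possibly empty).
#' @return Object of class `"pattern_tally"`: a list with `entries` (data
#'   frame `f`, `key`, `n` over the distinct non-empty patterns) and
#'   `families` (named integer vector: total families per size, including
#'   non-mutant ones).
#' @examples
#' t <- pattern_tally(rep(20, 3), list(c(1), c(1), c(2, 10)))
#' tally_summary(t)
#' @export
pattern_tally <- function(f, patterns) {
  stopifnot(length(f) == length(patterns))
  f <- as.integer(f)
  keys <- vapply(patterns, .sizes_key, character(1))
  sums <- vapply(patterns, function(s) sum(as.integer(s)), integer(1))
  if (any(sums > f))
    stop("pattern sizes sum to more than the family size in family ",
         which(sums > f)[1L])
  families <- table(factor(f, levels = sort(unique(f))))
  nonempty <- nzchar(keys)
  if (any(nonempty)) {
    agg <- stats::aggregate(list(n = rep(1L, sum(nonempty))),
                            by = list(f = f[nonempty], key = keys[nonempty]),
                            FUN = sum)
    agg <- agg[order(agg$f, nchar(agg$key), agg$key), , drop = FALSE]
  } else {
    agg <- data.frame(f = integer(0), key = character(0), n = integer(0))
  }
  rownames(agg) <- NULL
  fam <- as.integer(families); names(fam) <- names(families)
  structure(list(entries = agg, families = fam), class = "pattern_tally")
}

#' Assemble a pattern tally from explicit entries
#'
#' Lower-level constructor used by the notation parser: entries give the
#' occurrence count of each distinct non-empty pattern, `families` the total
#' number of families (mutant plus non-mutant) per size.
#'
#' @param entries data frame with columns `f`, `key` (comma-separated sorted
#'   sizes) and `n`.
#' @param families named integer vector: family counts keyed by size.
#' @return A `"pattern_tally"` object.
#' @export
new_pattern_tally <- function(entries, families) {
  entries$f <- as.integer(entries$f)
  entries$n <- as.integer(entries$n)
  entries$key <- vapply(entries$key, function(k) .sizes_key(.key_sizes(k)), character(1))
  stopifnot(all(entries$n >= 1L), !is.null(names(families)))
  for (ff in unique(entries$f)) {
    nf <- sum(entries$n[entries$f == ff])
    tot <- families[as.character(ff)]
    if (is.na(tot) || tot < nf)
      stop("family count for size ", ff, " is below the tallied patterns")
    if (any(vapply(entries$key[entries$f == ff],
                   function(k) sum(.key_sizes(k)), integer(1)) > ff))
      stop("a pattern for size ", ff, " exceeds the family size")
  }
  entries <- entries[order(entries$f, nchar(entries$key), entries$key), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, families = families), class = "pattern_tally")
}

#' @export
print.pattern_tally <- function(x, ...) {
  cat("Pattern tally:", sum(x$families), "families,",
      sum(x$entries$n), "mutant families\n")
  cat(format_pattern_notation(x), sep = "\n")
  invisible(x)
}

#' Family sizes present in a tally
#' @param tally a `"pattern_tally"`.
#' @return Sorted integer vector of family sizes.
#' @export
tally_sizes <- function(tally) sort(as.integer(names(tally$families)))

#' Screen summary statistics of a tally
#'
#' @param tally a `"pattern_tally"`.
#' @return List with `m_t` (total mutations), `n_m` (total mutant lines),
#'   `lines` (total lines screened), `mutant_families`, `families`, and the
#'   classical overall rate `mu_tilde = n_m / lines`.
#' @export
tally_summary <- function(tally) {
  e <- tally$entries
  sizes <- lapply(e$key, .key_sizes)
  m_t <- sum(e$n * lengths(sizes))
  n_m <- sum(e$n * vapply(sizes, sum, integer(1)))
  lines <- sum(as.integer(names(tally$families)) * tally$families)
  list(m_t = m_t, n_m = n_m, lines = lines,
       mutant_families = sum(e$n),
       families = sum(tally$families),
       mu_tilde = if (lines > 0) n_m / lines else 0)
}

#' Distribution of families by mutation count
#'
#' Tables families by the number of independent mutations they carry, the
#' shape in which screen summaries are usually reported.
#'
#' @param tally a `"pattern_tally"`.
#' @return Data frame with columns `mutations` and `families`.
#' @export
tally_mutation_distribution <- function(tally) {
  e <- tally$entries
  k <- lengths(lapply(e$key, .key_sizes))
  kmax <- max(c(0L, k))
  out <- integer(kmax + 1L)
  for (i in seq_along(k)) out[k[i] + 1L] <- out[k[i] + 1L] + e$n[i]
  out[1L] <- sum(tally$families) - sum(e$n)
  data.frame(mutations = 0:kmax, families = out)
}

#' Enumerate all mutation patterns for a family size
#'
#' Lists every multiset of positive integers with sum at most `f`, including
#' the empty pattern.  Combinatorial guard: `f <= 8`.
#'
#' @param f family size, at most 8.
#' @return List of integer vectors (sorted non-decreasing), first element the
#'   empty pattern.
#' @export
enumerate_patterns <- function(f) {
  if (f > 8) stop("pattern enumeration is limited to f <= 8")
  f <- as.integer(f)
  out <- list(integer(0))
  rec <- function(prefix, lo, rem) {
    for (s in lo:rem) {
      out[[length(out) + 1L]] <<- c(prefix, s)
      if (rem - s >= s) rec(c(prefix, s), s, rem - s)
    }
  }
  if (f >= 1L) rec(integer(0), 1L, f)
  out
}
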