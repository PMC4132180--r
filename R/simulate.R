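## Forward simulator of complete screening experiments with known ground
## truth: genealogies from the coalescent engine, Poisson mutations on
## ancestral branches, masking, F3 binomial counts, and allelism crosses.

#' Configuration of a synthetic screening experiment
#'
#' Defaults emulate the original study design: families of 2-35 recorded
#' lines (35 initiated, independent attrition tuned to a mean of about 28
#' recorded lines), at least 40 F3 offspring per line with mean about 118, a
#' baseline z/z proportion of 0.175 (z/z homozygotes are slightly less fit
#' than the 1/3 Mendelian expectation), six-interval rates at the
#' all-lethality maximum-likelihood estimates, and the optimal germline
#' dynamics (`D = 38`, `n5 = 6`, `n8 = 8`).
#'
#' @param n_families number of families.
#' @param lines `NULL` for the default attrition model, a single integer for
#'   a fixed family size, or a `function(n)` drawing `n` family sizes.
#' @param initiated,survival attrition model: recorded lines per family are
#'   `rbinom(1, initiated, survival)` clamped to `[2, 35]`.
#' @param offspring_min,offspring_mean F3 offspring per line:
#'   `offspring_min + rpois(offspring_mean - offspring_min)`.
#' @param p0 baseline z/z proportion among F3 offspring, in `(0, 1/3]`.
#' @param u true per-interval mutation rates.
#' @param partition an [interval_partition()].
#' @param dyn a [germline_dynamics()] with the same `D`.
#' @param lethality `function(n)` drawing lethalities of new mutations in
#'   `[0.97, 1]` (default: mass 0.3 at complete lethality, otherwise uniform).
#' @param cross_total offspring examined per allelism cross.
#' @param candidate_frac a line enters the allelism test when its observed
#'   z/z fraction is at most this value.
#' @param extra_edge_frac crosses beyond the connecting chain, as a fraction
#'   of the number of candidate lines.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_families = 9594,
                         lines = NULL, initiated = 35, survival = 0.81,
                         offspring_min = 40, offspring_mean = 118,
                         p0 = 0.175,
                         u = c(67.371, 1.258, 0.021, 0.031, 0.177, 1.954) * 1e-3,
                         partition = interval_partition(c(1, 2, 3, 14, -5), 38),
                         dyn = germline_dynamics(38, 6, 8),
                         lethality = function(n)
                           ifelse(stats::runif(n) < 0.3, 1,
                                  stats::runif(n, 0.97, 1)),
                         cross_total = 100, candidate_frac = 0.08,
                         extra_edge_frac = 1 / 3) {
  stopifnot(p0 > 0, p0 <= 1 / 3, dyn$D == partition$D)
  u <- .rates(u, partition)
  structure(list(n_families = n_families, lines = lines,
                 initiated = initiated, survival = survival,
                 offspring_min = offspring_min, offspring_mean = offspring_mean,
                 p0 = p0, u = u, partition = partition, dyn = dyn,
                 lethality = lethality, cross_total = cross_total,
                 candidate_frac = candidate_frac,
                 extra_edge_frac = extra_edge_frac),
            class = "synth_config")
}

.draw_family_size <- function(config) {
  if (is.function(config$lines)) return(as.integer(config$lines(1L)))
  if (!is.null(config$lines)) return(as.integer(config$lines))
  min(35L, max(2L, stats::rbinom(1L, config$initiated, config$survival)))
}

## Backward genealogy of f lines with Poisson mutation placement: at each
## division every ancestral branch draws Poisson(u_{I(d)}) mutations carried
## by all its sampled descendants.
.genealogy_mutations <- function(f, config) {
  dyn <- config$dyn
  D <- dyn$D
  udiv <- config$u[division_interval_map(config$partition)]
  lin <- seq_len(f)                 # leaf -> current lineage index (1..A)
  muts <- list()
  for (d in D:1) {
    A <- max(lin)
    if (udiv[d] > 0) {
      nm <- stats::rpois(A, udiv[d])
      for (l in which(nm > 0L)) {
        members <- which(lin == l)
        for (k in seq_len(nm[l]))
          muts[[length(muts) + 1L]] <- list(division = d, carriers = members)
      }
    }
    if (d > 1L) {
      ndiv <- dyn$npop[d] - dyn$npar[d]
      slots <- sample.int(dyn$npop[d], A)
      par <- ifelse(slots <= 2L * ndiv, (slots + 1L) %/% 2L, slots - ndiv)
      grp <- match(par, unique(par))
      lin <- grp[lin]
    }
  }
  muts
}

#' Simulate one family (lines plus ground truth)
#'
#' Simulates the sperm genealogy of the family's lines, drops Poisson
#' mutations on its ancestral branches, applies masking (a line carrying
#' several mutations is attributed to the earliest-division one; mutations
#' left with no attributed carrier are recorded as masked), draws a lethality
#' for each mutation, and generates binomial F3 counts: non-carrier lines use
#' the baseline z/z proportion `p0`, carriers of a mutation of lethality `d`
#' use `(1 - d) * p0 / 0.175` (so the observed lethality scale matches the
#' definition used when scoring lines).
#'
#' @param config a [synth_config()].
#' @param f optional family size override.
#' @return List with `lines` (data frame `line`, `zz`, `total`, `balancer`)
#'   and `truth` (list: `f`, per-mutation `division`, `lethality`, original
#'   and attributed carriers, `masked` flag; per-line attributed mutation
#'   index `line_mutation`, `NA` for non-mutants).
#' @export
generate_family <- function(config, f = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(f)) f <- .draw_family_size(config)
  f <- as.integer(f)
  muts <- .genealogy_mutations(f, config)
  ## Masking: attribute each carrier line to its earliest-division mutation.
  ord <- order(vapply(muts, `[[`, 0L, "division"))
  assigned <- rep(NA_integer_, f)
  truth_muts <- list()
  for (i in ord) {
    eff <- muts[[i]]$carriers[is.na(assigned[muts[[i]]$carriers])]
    idx <- length(truth_muts) + 1L
    if (length(eff)) assigned[eff] <- idx
    truth_muts[[idx]] <- list(division = muts[[i]]$division,
                              carriers = muts[[i]]$carriers,
                              attributed = eff,
                              size = length(eff),
                              masked = length(eff) == 0L)
  }
  nmut <- length(truth_muts)
  d_let <- if (nmut) config$lethality(nmut) else numeric(0)
  for (i in seq_len(nmut)) truth_muts[[i]]$lethality <- d_let[i]
  total <- config$offspring_min +
    stats::rpois(f, config$offspring_mean - config$offspring_min)
  p <- rep(config$p0, f)
  carrier <- !is.na(assigned)
  if (any(carrier)) {
    dl <- d_let[assigned[carrier]]
    p[carrier] <- pmin(1, pmax(0, (1 - dl) * config$p0 / 0.175))
  }
  zz <- stats::rbinom(f, total, p)
  list(lines = data.frame(line = seq_len(f), zz = zz, total = total,
                          balancer = FALSE),
       truth = list(f = f, mutations = truth_muts, line_mutation = assigned))
}

#' Simulate allelism crosses for one family
#'
#' Candidate lines (observed z/z fraction at most `candidate_frac`) are
#' first connected by a chain of crosses in order of observed z/z fraction
#' (lines carrying the same mutation have similar fractions, so the chain
#' keeps them adjacent) plus a few random extra edges.  As in the real
#' experiment, ambiguities are then resolved adaptively: the provisional
#' delineation is computed from the first-round crosses, and one additional
#' cross is performed between representatives of every pair of provisional
#' groups not yet connected by a cross.
#'
#' A cross between two lines attributed to the same mutation is
#' non-complementing (z/z proportion as in the parental lines); any other
#' pair - different mutations, a mutant with a non-mutant, or a mutant with
#' a line whose second mutation is masked - complements (baseline `p0`).
#'
#' @param family a family from [generate_family()].
#' @param config a [synth_config()].
#' @param screen a [screen_config()] used for the provisional delineation of
#'   the resolution round.
#' @return Data frame of crosses (`line_a`, `line_b`, `zz`, `total`),
#'   possibly empty.
#' @export
simulate_crosses <- function(family, config, screen = screen_config()) {
  lines <- family$lines
  truth <- family$truth
  frac <- lines$zz / lines$total
  cand <- lines$line[frac <= config$candidate_frac]
  empty <- data.frame(line_a = integer(0), line_b = integer(0),
                      zz = integer(0), total = integer(0))
  if (length(cand) < 2L) return(empty)

  mut_of <- truth$line_mutation
  n3 <- config$cross_total
  draw <- function(pairs) {
    zz3 <- integer(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1L]; b <- pairs[i, 2L]
      same <- !is.na(mut_of[a]) && !is.na(mut_of[b]) && mut_of[a] == mut_of[b]
      p <- if (same) {
        dl <- truth$mutations[[mut_of[a]]]$lethality
        min(1, max(0, (1 - dl) * config$p0 / 0.175))
      } else config$p0
      zz3[i] <- stats::rbinom(1L, n3, p)
    }
    data.frame(line_a = pairs[, 1L], line_b = pairs[, 2L],
               zz = zz3, total = rep(n3, nrow(pairs)))
  }

  ord <- cand[order(frac[match(cand, lines$line)], lines$line[match(cand, lines$line)])]
  pairs <- cbind(ord[-length(ord)], ord[-1L])
  n_extra <- floor(length(cand) * config$extra_edge_frac)
  if (n_extra > 0L && length(cand) > 2L) {
    all_pairs <- t(utils::combn(sort(cand), 2L))
    key <- paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
    avail <- which(!(paste(all_pairs[, 1L], all_pairs[, 2L]) %in% key))
    if (length(avail))
      pairs <- rbind(pairs, all_pairs[sample(avail, min(n_extra, length(avail))), ,
                                      drop = FALSE])
  }
  crosses <- draw(pairs)

  ## Resolution round: connect provisional groups pairwise.
  del <- delineate_mutations(lines, crosses, screen)
  G <- length(del$groups)
  if (G >= 2L) {
    have <- paste(pmin(crosses$line_a, crosses$line_b),
                  pmax(crosses$line_a, crosses$line_b))
    reps <- vapply(del$groups, function(g) {
      mem <- as.integer(g$members)
      mem[which.max(lines$total[match(mem, lines$line)])]
    }, integer(1))
    extra <- list()
    for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
      k <- paste(min(reps[i], reps[j]), max(reps[i], reps[j]))
      if (!(k %in% have)) {
        extra[[length(extra) + 1L]] <- c(reps[i], reps[j])
        have <- c(have, k)
      }
    }
    if (length(extra))
      crosses <- rbind(crosses, draw(do.call(rbind, extra)))
  }
  crosses
}

#' Simulate a complete screening experiment
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the experiment is reproducible given
#'   `(config, seed)`.
#' @return Object of class `"synth_experiment"`: list with `lines` and
#'   `crosses` data frames (with a `family` column), `truth` (per-family
#'   ground truth) and `seed`.
#' @export
generate_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  lines_list <- vector("list", config$n_families)
  cross_list <- vector("list", config$n_families)
  truth <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    fam <- generate_family(config)
    cr <- simulate_crosses(fam, config)
    fam$lines <- cbind(family = i, fam$lines)
    lines_list[[i]] <- fam$lines
    if (nrow(cr)) cross_list[[i]] <- cbind(family = i, cr)
    truth[[i]] <- fam$truth
  }
  crosses <- do.call(rbind, cross_list[!vapply(cross_list, is.null, TRUE)])
  if (is.null(crosses))
    crosses <- data.frame(family = integer(0), line_a = integer(0),
                          line_b = integer(0), zz = integer(0),
                          total = integer(0))
  lines <- do.call(rbind, lines_list)
  if (is.null(lines))
    lines <- data.frame(family = integer(0), line = integer(0),
                        zz = integer(0), total = integer(0),
                        balancer = logical(0))
  structure(list(lines = lines, crosses = crosses,
                 truth = truth, seed = seed, config = config),
            class = "synth_experiment")
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat("Synthetic screening experiment:", length(x$truth), "families,",
      nrow(x$lines), "lines,", nrow(x$crosses), "crosses\n")
  invisible(x)
}

#' Ground-truth pattern tally of a synthetic experiment
#'
#' Bypasses the screen: tallies the true (post-masking) mutation patterns in
#' the given lethality window, one entry per simulated family.
#'
#' @param experiment a `"synth_experiment"`.
#' @param window lethality window `c(lo, hi)` (top-closed when `hi >= 1`).
#' @return A [pattern_tally()].
#' @export
truth_tally <- function(experiment, window = c(0.97, 1)) {
  stopifnot(inherits(experiment, "synth_experiment"))
  f <- vapply(experiment$truth, `[[`, 0L, "f")
  pats <- lapply(experiment$truth, function(tr) {
    sizes <- integer(0)
    for (mu in tr$mutations)
      if (!mu$masked && .in_window(mu$lethality, window))
        sizes <- c(sizes, mu$size)
    sizes
  })
  pattern_tally(f, pats)
}
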