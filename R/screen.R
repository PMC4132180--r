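## Allelism screen: from raw line / cross counts to QC-filtered families,
## delineated mutations, and pattern tallies.

#' Screen configuration
#'
#' @param alpha overall significance level of the allelism tests within a
#'   family; each cross is tested at `alpha / m` where `m` is the number of
#'   crosses performed in the family.
#' @param min_offspring minimum F3 offspring for a line to qualify.
#' @param candidate_d lethality threshold above which a line is a candidate
#'   mutant (a line is a candidate when its z/z fraction is at most
#'   `1 - candidate_d`).
#' @param untested_removal_d lethality threshold above which an untested line
#'   is removed from its family: the identity of its mutation cannot be
#'   determined without a cross.
#' @param windows list of lethality windows `c(lo, hi)`; windows are
#'   closed-open `[lo, hi)` except when `hi >= 1`, which closes the top.
#' @return Object of class `"screen_config"`.
#' @export
screen_config <- function(alpha = 0.10, min_offspring = 40,
                          candidate_d = 0.92, untested_removal_d = 0.92,
                          windows = list(c(0.99, 1), c(0.98, 0.99),
                                         c(0.97, 0.98))) {
  stopifnot(alpha > 0, alpha < 1, min_offspring >= 1)
  structure(list(alpha = alpha, min_offspring = min_offspring,
                 candidate_d = candidate_d,
                 untested_removal_d = untested_removal_d,
                 windows = windows),
            class = "screen_config")
}

#' Per-line z/z fraction and lethality
#'
#' @param zz number of z/z offspring.
#' @param total total F3 offspring (positive).
#' @return List with `zz_fraction` and the recessive lethality
#'   `d = 1 - zz_fraction`.
#' @examples
#' line_stats(29, 112)$zz_fraction  # 0.259
#' @export
line_stats <- function(zz, total) {
  if (any(total <= 0)) stop("'total' must be positive")
  if (any(zz < 0) || any(zz > total)) stop("'zz' must be in 0..total")
  fr <- zz / total
  list(zz_fraction = fr, d = 1 - fr)
}

#' Quality-control filter for one family
#'
#' Applies the line-level QC rules: a line is dropped when it produced
#' balancer-genotype offspring in the F3 (the mother cannot have been virgin)
#' or fewer than `min_offspring` total offspring.  When cross information is
#' available (`tested` supplied), untested lines whose lethality reaches
#' `untested_removal_d` are also dropped: their mutation identity cannot be
#' determined.  Families with fewer than two surviving lines are rejected.
#'
#' @param lines data frame with columns `line`, `zz`, `total` and optionally
#'   `balancer` (logical).
#' @param config a [screen_config()].
#' @param tested optional vector of line ids used in crosses; `NULL` means
#'   cross information is not yet available and the untested-removal rule is
#'   not applied.
#' @return List with `ok` (logical), `lines` (surviving rows), `dropped`
#'   (data frame of dropped rows with a `reason` column) and `reason` (for a
#'   rejected family).
#' @export
family_qc <- function(lines, config = screen_config(), tested = NULL) {
  stopifnot(is.data.frame(lines), all(c("line", "zz", "total") %in% names(lines)))
  if (any(lines$zz > lines$total))
    stop("zz > total for line ", lines$line[which(lines$zz > lines$total)[1L]])
  reason <- rep(NA_character_, nrow(lines))
  if ("balancer" %in% names(lines))
    reason[which(as.logical(lines$balancer))] <- "balancer offspring in F3"
  reason[is.na(reason) & lines$total < config$min_offspring] <-
    "fewer than minimum F3 offspring"
  if (!is.null(tested)) {
    d <- 1 - lines$zz / lines$total
    hot <- is.na(reason) & d >= config$untested_removal_d
    ## The identity of an untested high-lethality line is undeterminable only
    ## when there are other such lines it could have been crossed with; a
    ## sole high-lethality line is a single mutation by itself.
    if (sum(hot) >= 2L) {
      untested_hot <- hot & !(lines$line %in% tested)
      reason[untested_hot] <- "untested line above lethality threshold"
    }
  }
  keep <- is.na(reason)
  dropped <- lines[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  kept <- lines[keep, , drop = FALSE]
  if (nrow(kept) < 2L) {
    return(list(ok = FALSE, lines = kept, dropped = dropped,
                reason = "too few lines"))
  }
  list(ok = TRUE, lines = kept, dropped = dropped, reason = NULL)
}

#' Allelism (complementation) likelihood-ratio statistic
#'
#' Tests whether two mutant lines carry the same mutation: under the null the
#' two parental lines and their cross share one z/z offspring proportion;
#' under the alternative the cross has its own.  The statistic is the
#' binomial deviance between the pooled and split fits and is asymptotically
#' chi-square with one degree of freedom.
#'
#' @param z1,n1 z/z and total offspring of parental line 1.
#' @param z2,n2 the same for parental line 2.
#' @param z3,n3 the same for the cross.
#' @return The likelihood-ratio statistic (non-negative; `0 * log 0` taken
#'   as 0).
#' @export
allelism_lr <- function(z1, n1, z2, n2, z3, n3) {
  ns <- c(n1, n2, n3)
  zs <- c(z1, z2, z3)
  if (any(ns <= 0)) stop("all totals must be positive")
  if (any(zs < 0) || any(zs > ns)) stop("counts must satisfy 0 <= z <= n")
  binll <- function(z, n) {
    ll <- 0
    if (z > 0) ll <- ll + z * log(z / n)
    if (z < n) ll <- ll + (n - z) * log(1 - z / n)
    ll
  }
  lr <- 2 * (binll(z1 + z2, n1 + n2) + binll(z3, n3) -
             binll(z1 + z2 + z3, n1 + n2 + n3))
  max(lr, 0)
}

#' Delineate mutations within a family from allelism crosses
#'
#' Each performed cross is tested at level `alpha / m` (`m` = number of
#' crosses in the family).  Lines joined by non-significant crosses are merged
#' into one mutation (union over the complementation-failure graph);
#' significant crosses separate mutations.  A conflict (a significant cross
#' between two lines already connected through non-significant crosses) is
#' resolved deterministically by deleting the largest-statistic
#' non-significant edge on the connecting path, and is reported.
#'
#' @param lines data frame of the family's qualified lines (`line`, `zz`,
#'   `total`).
#' @param crosses data frame of crosses (`line_a`, `line_b`, `zz`, `total`).
#' @param config a [screen_config()].
#' @return List with `groups` (list of mutation groups: `members`, `size`,
#'   `zz_pooled`, `d`), `crosses` (input annotated with `lr`, `p_value`,
#'   `significant`), `level` (the per-cross level used) and `conflicts`
#'   (data frame of resolved conflicts).
#' @export
delineate_mutations <- function(lines, crosses, config = screen_config()) {
  stopifnot(is.data.frame(lines))
  ## A family whose only candidate mutant line could not be crossed still
  ## carries exactly one identifiable mutation: that line by itself.
  singleton <- function() {
    cand <- which(lines$zz / lines$total <= 1 - config$candidate_d)
    if (length(cand) != 1L) return(list())
    row <- lines[cand, ]
    zzp <- row$zz / row$total
    list(list(members = as.character(row$line), size = 1L,
              zz_pooled = zzp, d = 1 - zzp))
  }
  if (is.null(crosses) || nrow(crosses) == 0L) {
    return(list(groups = singleton(), crosses = crosses, level = NA_real_,
                conflicts = NULL))
  }
  stopifnot(all(c("line_a", "line_b", "zz", "total") %in% names(crosses)))
  m <- nrow(crosses)
  level <- config$alpha / m
  stat <- p <- numeric(m)
  for (i in seq_len(m)) {
    a <- crosses$line_a[i]; b <- crosses$line_b[i]
    ra <- lines[match(a, lines$line), ]
    rb <- lines[match(b, lines$line), ]
    if (any(is.na(ra$line)) || any(is.na(rb$line)))
      stop("cross refers to unknown line ", if (is.na(ra$line)) a else b)
    stat[i] <- allelism_lr(ra$zz, ra$total, rb$zz, rb$total,
                           crosses$zz[i], crosses$total[i])
    p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
  }
  crosses$lr <- stat
  crosses$p_value <- p
  crosses$significant <- p < level

  verts <- unique(c(as.character(crosses$line_a), as.character(crosses$line_b)))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  ns <- which(!crosses$significant)
  if (length(ns)) {
    g <- igraph::add_edges(g, rbind(as.character(crosses$line_a[ns]),
                                    as.character(crosses$line_b[ns])))
    igraph::E(g)$lr <- crosses$lr[ns]
    igraph::E(g)$cross <- ns
  }
  conflicts <- list()
  repeat {
    memb <- igraph::components(g)$membership
    sig <- which(crosses$significant)
    internal <- sig[memb[as.character(crosses$line_a[sig])] ==
                    memb[as.character(crosses$line_b[sig])]]
    if (!length(internal)) break
    i <- internal[which.max(crosses$lr[internal])]
    path <- igraph::shortest_paths(
      g, from = as.character(crosses$line_a[i]),
      to = as.character(crosses$line_b[i]), output = "epath")$epath[[1L]]
    drop_edge <- path[which.max(igraph::E(g)$lr[as.integer(path)])]
    conflicts[[length(conflicts) + 1L]] <- data.frame(
      sig_a = crosses$line_a[i], sig_b = crosses$line_b[i],
      sig_lr = crosses$lr[i],
      removed_cross = igraph::E(g)$cross[as.integer(drop_edge)])
    g <- igraph::delete_edges(g, drop_edge)
  }
  memb <- igraph::components(g)$membership
  groups <- list()
  for (k in sort(unique(memb))) {
    members <- verts[memb == k]
    rows <- lines[match(members, as.character(lines$line)), , drop = FALSE]
    zzp <- sum(rows$zz) / sum(rows$total)
    groups[[length(groups) + 1L]] <-
      list(members = members, size = length(members),
           zz_pooled = zzp, d = 1 - zzp)
  }
  list(groups = groups, crosses = crosses, level = level,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else NULL)
}

.in_window <- function(d, window) {
  lo <- window[1L]; hi <- window[2L]
  if (hi >= 1) d >= lo & d <= 1 else d >= lo & d < hi
}

#' Extract a family's mutation pattern for one lethality window
#'
#' @param groups mutation groups from [delineate_mutations()].
#' @param window lethality window `c(lo, hi)`; closed-open except at the top
#'   (`hi >= 1` closes the interval, and a minimum-lethality threshold `d >=
#'   lo` is expressed as `c(lo, 1)`).
#' @param f family size (number of qualified lines), used to enforce the
#'   one-mutation-per-line constraint.
#' @return Integer vector of mutation sizes (the pattern), possibly empty.
#' @export
extract_pattern <- function(groups, window, f) {
  sizes <- integer(0)
  for (grp in groups)
    if (.in_window(grp$d, window)) sizes <- c(sizes, grp$size)
  sizes <- .canon_sizes(sizes)
  if (sum(sizes) > f)
    stop("data-integrity error: pattern sizes sum to ", sum(sizes),
         " for a family of ", f, " lines")
  sizes
}

#' Screen a whole experiment: QC, delineation, per-family groups
#'
#' Runs [family_qc()] and [delineate_mutations()] family by family.
#'
#' @param lines data frame of all lines (`family`, `line`, `zz`, `total`,
#'   optional `balancer`).
#' @param crosses data frame of all crosses (`family`, `line_a`, `line_b`,
#'   `zz`, `total`), possibly empty.
#' @param config a [screen_config()].
#' @return List of per-family records: `family`, `ok`, `f`, `groups`,
#'   `dropped`, `reason`.
#' @export
screen_families <- function(lines, crosses, config = screen_config()) {
  stopifnot(is.data.frame(lines), "family" %in% names(lines))
  out <- list()
  for (fam in unique(lines$family)) {
    fl <- lines[lines$family == fam, , drop = FALSE]
    fc <- if (!is.null(crosses) && nrow(crosses))
      crosses[crosses$family == fam, , drop = FALSE] else NULL
    tested <- if (!is.null(fc) && nrow(fc))
      unique(c(fc$line_a, fc$line_b)) else character(0)
    qc <- family_qc(fl, config, tested = tested)
    if (!qc$ok) {
      out[[length(out) + 1L]] <- list(family = fam, ok = FALSE, f = nrow(qc$lines),
                                      groups = list(), dropped = qc$dropped,
                                      reason = qc$reason)
      next
    }
    fc_kept <- if (!is.null(fc) && nrow(fc))
      fc[fc$line_a %in% qc$lines$line & fc$line_b %in% qc$lines$line, , drop = FALSE]
    else NULL
    del <- delineate_mutations(qc$lines, fc_kept, config)
    out[[length(out) + 1L]] <- list(family = fam, ok = TRUE, f = nrow(qc$lines),
                                    groups = del$groups, dropped = qc$dropped,
                                    reason = NULL, conflicts = del$conflicts)
  }
  out
}

#' Tally the patterns of screened families in one lethality window
#'
#' @param screened list of per-family records from [screen_families()] (only
#'   families with `ok = TRUE` contribute).
#' @param window lethality window (see [extract_pattern()]).
#' @return List with `tally` (a [pattern_tally()]) and `summary`
#'   ([tally_summary()] output).
#' @export
tally_patterns <- function(screened, window) {
  keep <- Filter(function(r) isTRUE(r$ok), screened)
  if (!length(keep)) {
    t <- pattern_tally(integer(0), list())
    return(list(tally = t, summary = tally_summary(t)))
  }
  f <- vapply(keep, function(r) as.integer(r$f), integer(1))
  pats <- lapply(keep, function(r) extract_pattern(r$groups, window, r$f))
  t <- pattern_tally(f, pats)
  list(tally = t, summary = tally_summary(t))
}

#' Exclude families with a high fraction of mutant lines
#'
#' Safeguard against sporadic pre-existing mutations: families whose fraction
#' of mutant lines (within the lethality window) reaches `threshold` are
#' removed before re-testing the rate hypotheses.
#'
#' @inheritParams tally_patterns
#' @param threshold mutant-line fraction in `(0, 1]`; a family is excluded
#'   when `sum(sizes) / f >= threshold`.
#' @return List with `kept` (family records), `excluded` (count) and
#'   `excluded_families` (their ids).
#' @export
exclude_high_mutant_families <- function(screened, threshold, window) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- list(); excl <- character(0)
  for (r in screened) {
    if (isTRUE(r$ok)) {
      sizes <- extract_pattern(r$groups, window, r$f)
      if (sum(sizes) / r$f >= threshold) {
        excl <- c(excl, as.character(r$family))
        next
      }
    }
    keep[[length(keep) + 1L]] <- r
  }
  list(kept = keep, excluded = length(excl), excluded_families = excl)
}
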