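test_that("line statistics follow the lethality definition", {
  s <- line_stats(29, 112)
  expect_equal(round(s$zz_fraction, 3), 0.259)
  expect_equal(s$d, 1 - 29 / 112)
  expect_equal(round(line_stats(3, 90)$zz_fraction, 3), 0.033)
  s0 <- line_stats(0, 70)
  expect_identical(s0$zz_fraction, 0)
  expect_identical(s0$d, 1)
  expect_error(line_stats(1, 0), "positive")
})

test_that("initial family QC matches the worked example", {
  ## 30 lines initiated; some lost before F3, one with balancer offspring,
  ## two with too few offspring: 17 recorded lines remain
  raw <- family140_raw()
  qc <- family_qc(raw, screen_config())
  expect_true(qc$ok)
  expect_identical(nrow(qc$lines), 17L)
  expect_identical(sort(qc$dropped$reason),
                   sort(c("balancer offspring in F3",
                          rep("fewer than minimum F3 offspring", 2))))
})

test_that("untested high-lethality lines are removed once crosses exist", {
  cfgs <- screen_config()
  lines <- data.frame(line = 1:4, zz = c(0, 1, 1, 20), total = c(100, 100, 90, 110))
  ## lines 1-3 exceed the lethality threshold; line 3 was never crossed
  qc <- family_qc(lines, cfgs, tested = c(1, 2))
  expect_identical(qc$lines$line, c(1L, 2L, 4L))
  expect_identical(qc$dropped$reason, "untested line above lethality threshold")
  ## without cross information the rule is not applied
  qc2 <- family_qc(lines, cfgs)
  expect_identical(nrow(qc2$lines), 4L)
  ## a sole high-lethality line is kept: its identity is determined
  lines3 <- data.frame(line = 1:3, zz = c(0, 20, 18), total = c(100, 100, 90))
  qc3 <- family_qc(lines3, cfgs, tested = integer(0))
  expect_identical(nrow(qc3$lines), 3L)
})

test_that("families with fewer than two surviving lines are rejected", {
  one <- data.frame(line = 1, zz = 0, total = 100)
  qc <- family_qc(one, screen_config())
  expect_false(qc$ok)
  expect_identical(qc$reason, "too few lines")
})

test_that("allelism statistic is the pooled-vs-split binomial deviance", {
  ## equal proportions: no evidence of different mutations
  expect_equal(allelism_lr(1, 10, 1, 10, 2, 20), 0)
  expect_equal(allelism_lr(0, 50, 0, 60, 0, 100), 0)
  ## independent evaluation from the three binomial log-likelihood terms
  ## (the two all-zero parental terms contribute 0 under the 0 log 0 rule)
  ll <- function(z, n, p) z * log(p) + (n - z) * log(1 - p)
  expect_equal(allelism_lr(0, 110, 0, 56, 10, 100),
               2 * (ll(10, 100, 0.1) - ll(10, 266, 10 / 266)),
               tolerance = 1e-12)
  expect_error(allelism_lr(1, 10, 1, 0, 1, 10), "positive")
})

test_that("allelism statistic matches a brute-force deviance on random counts", {
  set.seed(21)
  dev <- function(z, n) {
    p <- z / n
    s <- 0
    if (z > 0) s <- s + z * log(p)
    if (z < n) s <- s + (n - z) * log(1 - p)
    s
  }
  for (rep in 1:1000) {
    n <- sample(20:200, 3, replace = TRUE)
    z <- stats::rbinom(3, n, stats::runif(1, 0, 0.3))
    got <- allelism_lr(z[1], n[1], z[2], n[2], z[3], n[3])
    want <- 2 * (dev(z[1] + z[2], n[1] + n[2]) + dev(z[3], n[3]) -
                 dev(sum(z), sum(n)))
    expect_lt(abs(got - max(want, 0)), 1e-9)
  }
})

test_that("allelism test type-I error is near nominal under the null", {
  set.seed(22)
  reps <- 5000
  alpha <- 0.05
  p0 <- 0.175
  rej <- 0
  for (r in seq_len(reps)) {
    z1 <- stats::rbinom(1, 118, p0)
    z2 <- stats::rbinom(1, 118, p0)
    z3 <- stats::rbinom(1, 100, p0)
    lr <- allelism_lr(z1, 118, z2, 118, z3, 100)
    if (stats::pchisq(lr, 1, lower.tail = FALSE) < alpha) rej <- rej + 1
  }
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(rej / reps - alpha), 3 * se)
})

test_that("delineation merges complementation failures and splits the rest", {
  cfgs <- screen_config(alpha = 0.10)
  ## two planted mutations: lines 1-3 share one (lethality 1), lines 4-5
  ## another (0.98); crosses within groups non-complementing, across groups
  ## complementing at the baseline z/z proportion
  lines <- data.frame(line = 1:5, zz = c(0, 0, 0, 2, 3),
                      total = c(110, 120, 100, 100, 110))
  crosses <- data.frame(line_a = c(1, 2, 3, 4),
                        line_b = c(2, 3, 4, 5),
                        zz = c(0, 0, 18, 2), total = rep(100, 4))
  del <- delineate_mutations(lines, crosses, cfgs)
  expect_identical(length(del$groups), 2L)
  sizes <- sort(vapply(del$groups, `[[`, 0L, "size"))
  expect_identical(sizes, c(2L, 3L))
  g1 <- del$groups[[which(vapply(del$groups, `[[`, 0L, "size") == 3L)]]
  expect_identical(sort(g1$members), c("1", "2", "3"))
  expect_identical(g1$d, 1)
  ## all-non-significant crosses give a single group of all tested lines
  cr2 <- data.frame(line_a = c(1, 2, 3, 4), line_b = c(2, 3, 4, 5),
                    zz = c(0, 0, 1, 2), total = rep(100, 4))
  del2 <- delineate_mutations(lines, cr2, cfgs)
  expect_identical(length(del2$groups), 1L)
  expect_identical(del2$groups[[1]]$size, 5L)
})

test_that("a sole uncrossed candidate forms its own mutation group", {
  cfgs <- screen_config()
  lines <- data.frame(line = 1:3, zz = c(0, 20, 21), total = c(100, 100, 100))
  del <- delineate_mutations(lines, NULL, cfgs)
  expect_identical(length(del$groups), 1L)
  expect_identical(del$groups[[1]]$members, "1")
  expect_identical(del$groups[[1]]$size, 1L)
  ## no candidates at all: no groups
  none <- data.frame(line = 1:2, zz = c(20, 21), total = c(100, 100))
  expect_identical(delineate_mutations(none, NULL, cfgs)$groups, list())
})

test_that("delineation recovers planted groups across replicates", {
  cfgs <- screen_config(alpha = 0.10)
  set.seed(23)
  good <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    ## groups {1,2,3} (d = 1) and {4,5} (d = 0.98), baseline 0.175
    zzl <- c(stats::rbinom(3, 110, 0), stats::rbinom(2, 110, 0.02))
    lines <- data.frame(line = 1:5, zz = zzl, total = 110)
    pair_p <- function(a, b) {
      if ((a <= 3) == (b <= 3)) { if (a <= 3) 0 else 0.02 } else 0.175
    }
    pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5))
    crosses <- data.frame(line_a = pairs[, 1], line_b = pairs[, 2],
                          zz = apply(pairs, 1, function(pq)
                            stats::rbinom(1, 100, pair_p(pq[1], pq[2]))),
                          total = 100)
    del <- delineate_mutations(lines, crosses, cfgs)
    sizes <- sort(vapply(del$groups, `[[`, 0L, "size"))
    if (identical(sizes, c(2L, 3L))) good <- good + 1
  }
  expect_gte(good / reps, 0.95)
})

test_that("raising alpha never decreases the number of groups", {
  set.seed(24)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    lines <- data.frame(line = seq_len(k),
                        zz = stats::rbinom(k, 110, 0.01), total = 110)
    npair <- k - 1L
    crosses <- data.frame(line_a = seq_len(npair), line_b = 2:(npair + 1L),
                          zz = stats::rbinom(npair, 100,
                                             stats::runif(npair, 0, 0.2)),
                          total = 100)
    n_groups <- vapply(c(0.1, 0.3, 0.5), function(a) {
      length(delineate_mutations(lines, crosses,
                                 screen_config(alpha = a))$groups)
    }, 0L)
    expect_true(all(diff(n_groups) >= 0))
  }
})

test_that("delineation is invariant to line relabeling", {
  cfgs <- screen_config()
  lines <- data.frame(line = c(10, 20, 30, 40), zz = c(0, 0, 1, 2),
                      total = c(100, 110, 90, 100))
  crosses <- data.frame(line_a = c(10, 20, 30), line_b = c(20, 30, 40),
                        zz = c(0, 17, 1), total = 100)
  del <- delineate_mutations(lines, crosses, cfgs)
  relab <- c("10" = 7, "20" = 3, "30" = 9, "40" = 1)
  lines2 <- transform(lines, line = relab[as.character(line)])
  crosses2 <- transform(crosses, line_a = relab[as.character(line_a)],
                        line_b = relab[as.character(line_b)])
  del2 <- delineate_mutations(lines2, crosses2, cfgs)
  key <- function(del) sort(vapply(del$groups, function(g)
    paste(sort(g$members), collapse = "+"), ""))
  expect_identical(key(del2),
                   sort(vapply(del$groups, function(g)
                     paste(sort(relab[g$members]), collapse = "+"), "")))
})

test_that("pattern extraction respects lethality windows and the size bound", {
  groups <- list(list(members = "3", size = 1L, zz_pooled = 0, d = 1),
                 list(members = as.character(1:13), size = 13L,
                      zz_pooled = 0.0171, d = 1 - 0.0171))
  ## top window [99%, 100%]: only the fully lethal singleton qualifies
  expect_identical(extract_pattern(groups, c(0.99, 1), 17), 1L)
  ## minimum lethality 97%: both qualify
  expect_identical(extract_pattern(groups, c(0.97, 1), 17), c(1L, 13L))
  ## window [97%, 98%) excludes both
  expect_identical(extract_pattern(groups, c(0.97, 0.98), 17), integer(0))
  expect_identical(extract_pattern(list(), c(0.97, 1), 17), integer(0))
  big <- list(list(members = "1", size = 10L, zz_pooled = 0, d = 1),
              list(members = "2", size = 11L, zz_pooled = 0, d = 1))
  expect_error(extract_pattern(big, c(0.97, 1), 17), "data-integrity")
})

test_that("pattern tallies count mutant and non-mutant families", {
  ## size-20 collection: 11 <1>, one each <2>, <3>, <17>, two <1,1>
  f <- rep(20L, 111)
  pats <- c(rep(list(1L), 11), list(2L), list(3L), list(17L),
            rep(list(c(1L, 1L)), 2), rep(list(integer(0)), 95))
  t <- pattern_tally(f, pats)
  s <- tally_summary(t)
  expect_identical(s$mutant_families, 16L)
  expect_identical(s$families - s$mutant_families, 95L)
  expect_identical(s$m_t, 18L)
  expect_identical(s$n_m, 37L)
  d <- tally_mutation_distribution(t)
  expect_identical(d$families[d$mutations == 0], 95L)
  expect_identical(d$families[d$mutations == 2], 2L)
  ## empty input gives an all-zero summary
  s0 <- tally_summary(pattern_tally(integer(0), list()))
  expect_identical(s0$m_t, 0L)
  expect_identical(s0$mu_tilde, 0)
})

test_that("high-mutant-family exclusion is a monotone threshold rule", {
  mk <- function(f, sizes) list(family = paste0(f, paste(sizes, collapse = "_")),
                                ok = TRUE, f = f,
                                groups = lapply(sizes, function(s)
                                  list(members = as.character(seq_len(s)),
                                       size = s, zz_pooled = 0, d = 1)))
  fams <- list(mk(20, 18L), mk(20, 10L), mk(30, 27L), mk(20, integer(0)))
  win <- c(0.97, 1)
  ex90 <- exclude_high_mutant_families(fams, 0.90, win)
  expect_identical(ex90$excluded, 2L)   # 18/20 and 27/30 reach 90%
  ex100 <- exclude_high_mutant_families(fams, 1, win)
  expect_identical(ex100$excluded, 0L)
  counts <- vapply(c(1, 0.9, 0.5, 0.3),
                   function(th) exclude_high_mutant_families(fams, th, win)$excluded,
                   0L)
  expect_true(all(diff(counts) >= 0))
})
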