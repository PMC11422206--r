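test_that("outlier rule is single-pass mean +/- 2 SD", {
  # brute force: x = ten 0s and one 10 -> mean 0.909, SD 3.015, bound 6.94
  x <- c(rep(0, 10), 10)
  expect_equal(mean(x) + 2 * sd(x), 6.939, tolerance = 1e-3)
  out <- remove_outliers(x)
  expect_equal(out$removed, 11L)
  expect_equal(out$values, rep(0, 10))

  # brute force: upper bound 2.8 + 2 * 4.025 = 10.85 keeps the 10
  y <- c(1, 1, 1, 1, 10)
  expect_equal(remove_outliers(y)$removed, integer())

  expect_equal(remove_outliers(rep(3, 6))$removed, integer())
  expect_warning(pass <- remove_outliers(c(1, 2)), "fewer than 3")
  expect_equal(pass$values, c(1, 2))
})

test_that("route choice follows the assumption tests", {
  set.seed(11)
  v <- c(rnorm(200), rnorm(200), rnorm(200))
  g <- rep(c("A", "B", "C"), each = 200)
  expect_equal(route_test(v, g)$route, "parametric")

  set.seed(11)
  v2 <- c(rnorm(200), rexp(200), rnorm(200))
  expect_equal(route_test(v2, g)$route, "nonparametric")

  v3 <- c(rep(1, 50), rnorm(50), rnorm(50))
  g3 <- rep(c("A", "B", "C"), each = 50)
  expect_warning(r3 <- route_test(v3, g3), "zero-variance")
  expect_equal(r3$route, "nonparametric")
})

test_that("mixed ANOVA detects programmed group separation", {
  set.seed(20)
  pvals <- replicate(20, {
    d <- expand.grid(subject_id = sprintf("P%02d", 1:23),
                     session = c("S1", "S2"))
    d$group <- rep(c(rep("G1", 9), rep("G2", 14)), 2)
    d$value <- rnorm(nrow(d)) + ifelse(d$group == "G2", 3, 0)
    mixed_anova(d)$effects$p[1]
  })
  expect_true(all(pvals < 0.001))
})

test_that("mixed ANOVA separates session and group effects", {
  set.seed(21)
  d <- expand.grid(subject_id = sprintf("P%02d", 1:24),
                   session = c("S1", "S2"))
  d$group <- rep(rep(c("G1", "G2"), each = 12), 2)
  d$value <- rnorm(nrow(d), sd = 0.5) + ifelse(d$session == "S2", 2, 0)
  eff <- mixed_anova(d)$effects
  expect_gt(eff$p[eff$effect == "group"], 0.05)
  expect_lt(eff$p[eff$effect == "session"], 0.001)
  # two within-subject levels: sphericity trivially satisfied
  expect_match(mixed_anova(d)$sphericity, "trivially")
})

test_that("degenerate inputs to ANOVA are reported, not hidden", {
  d <- expand.grid(subject_id = sprintf("P%02d", 1:8),
                   session = c("S1", "S2"))
  d$group <- rep(rep(c("G1", "G2"), each = 4), 2)
  d$value <- 1
  out <- mixed_anova(d)
  expect_true(is.na(out$effects$F[1]) || out$effects$F[1] == 0)

  ow <- one_way_anova(rep(1:3, 3), rep(c("A", "B", "C"), each = 3))
  expect_equal(ow$F, 0)
  expect_equal(ow$p, 1)
  zw <- one_way_anova(c(0, 0, 10, 10), c("A", "A", "B", "B"))
  expect_true(zw$zero_within_variance)
})

test_that("pairwise comparisons apply the Bonferroni correction", {
  set.seed(30)
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("A", "B", "C"), each = 4)
  same <- pairwise_bonferroni(v, g, "parametric")
  expect_true(all(same$p_corrected == 1))

  # two groups: correction factor 1
  v2 <- c(rnorm(10), rnorm(10, 2))
  g2 <- rep(c("A", "B"), each = 10)
  two <- pairwise_bonferroni(v2, g2, "parametric")
  expect_equal(two$p_corrected, two$p_raw)

  # corrected p monotone in raw p and capped at 1
  v3 <- c(rnorm(8), rnorm(8, 0.5), rnorm(8, 4))
  g3 <- rep(c("A", "B", "C"), each = 8)
  res <- pairwise_bonferroni(v3, g3, "nonparametric")
  expect_true(all(res$p_corrected <= 1))
  expect_equal(order(res$p_raw), order(res$p_corrected))
  expect_true(all(res$p_corrected >= res$p_raw))
  expect_true(all(abs(res$effect_size) <= 1))
})

test_that("Cohen's d matches hand-computed pooled-SD values", {
  a <- c(-1, 0, 1); b <- c(0, 1, 2)   # means 0 and 1, both SD 1
  expect_equal(cohen_d(a, b)$d, -1)
  expect_equal(cohen_d(a, a)$d, 0)
  # brute force: means 0.5 and 2.5, pooled SD sqrt(1/3)
  d <- cohen_d(c(0, 0, 1, 1), c(2, 2, 3, 3))
  expect_equal(d$d, -2 / sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(d$magnitude, "large")
  expect_equal(cohen_d(c(0.1, 0.2, 0.1, 0.2),
                       c(0.15, 0.25, 0.15, 0.25))$magnitude, "large")
  expect_true(cohen_d(c(1, 1), c(1, 1))$flagged)
})

test_that("rank-biserial equals the dominance enumeration", {
  expect_equal(rank_biserial(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(rank_biserial(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(rank_biserial(c(1, 3, 5, 7), c(2, 4, 6, 8)), -0.25)
  expect_equal(rank_biserial(1:4, 1:4), 0)

  dominance <- function(a, b) {
    s <- 0
    for (x in a) for (y in b) s <- s + sign(x - y)
    s / (length(a) * length(b))
  }
  set.seed(40)
  for (rep in 1:200) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sample(0:5, na, replace = TRUE)  # small alphabet forces ties
    b <- sample(0:5, nb, replace = TRUE)
    expect_equal(rank_biserial(a, b), dominance(a, b))
  }
})

test_that("compare_groups reproduces a programmed separation pattern", {
  set.seed(50)
  subj <- sprintf("P%02d", 1:35)
  grp <- c(rep("G1", 9), rep("G2", 14), rep("G3", 12))
  d <- expand.grid(subject_id = subj, session = c("S1", "S2"),
                   stringsAsFactors = FALSE)
  d$group <- rep(grp, 2)
  d$value <- rnorm(nrow(d), sd = 1) +
    ifelse(d$group == "G1", 0, 6)  # G1 << G2 ~ G3
  cmp <- compare_groups(d)
  pw <- cmp$pairwise
  sig <- pw$p_corrected < 0.05
  expect_true(all(sig[pw$A == "G1"]))
  expect_false(any(sig[pw$A == "G2" & pw$B == "G3"]))
  expect_error(compare_groups(d[d$group == "G1", ]), "2 groups")
})
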