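test_that("TAS normalization equalizes run totals and preserves proportions", {
  set.seed(1)
  v <- matrix(rexp(60, rate = 1e-5), nrow = 10)
  q <- toy_quant(values = v, n_proteins = 10, n_bio = 2, n_tech = 1)
  norm <- tas_normalize(q)
  totals <- colSums(norm$values)
  expect_lt(diff(range(totals)), 1e-9 * mean(totals))
  # grand total preserved, proportions unchanged
  expect_equal(mean(totals), mean(colSums(v)))
  expect_equal(sweep(norm$values, 2, colSums(norm$values), "/"),
               sweep(v, 2, colSums(v), "/"), ignore_attr = TRUE)
  # idempotent; already-equal totals unchanged
  expect_equal(tas_normalize(norm)$values, norm$values)
  # a run with double the total of the others ends up scaled down 2x
  # relative to them: after normalization all cells coincide
  q2 <- toy_quant(values = matrix(c(rep(1, 20), rep(2, 4)), nrow = 4),
                  n_proteins = 4, n_bio = 2, n_tech = 1)
  n2 <- tas_normalize(q2)
  expect_equal(colSums(n2$values), rep(mean(c(rep(4, 5), 8)), 6),
               ignore_attr = TRUE)
  expect_lt(diff(range(n2$values)), 1e-12)
  # all-zero run is an error naming the run
  v[, 3] <- 0
  expect_error(tas_normalize(toy_quant(values = v, n_proteins = 10,
                                       n_bio = 2, n_tech = 1)),
               "all-zero")
})

test_that("pooled t-test matches the hand-computed textbook example", {
  # T1 = {1,2,3}, T2 = {4,5,6}, T3 repeats T1
  runs <- data.frame(run_id = paste0("r", 1:9), tissue = "cement",
                     extraction = "SDS",
                     time = rep(c("T1", "T2", "T3"), each = 3),
                     bio_rep = 1, tech_rep = 1:3)
  q <- quant_matrix(matrix(c(1, 2, 3, 4, 5, 6, 1, 2, 3), nrow = 1,
                           dimnames = list("p1", runs$run_id)), runs)
  d <- differential_test(q)
  t12 <- d[d$comparison == "T1vT2", ]
  expect_equal(t12$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(t12$df, 4)
  expect_equal(t12$p_value, 0.0213116, tolerance = 1e-5)
  expect_true(t12$significant)
  expect_equal(t12$direction, "up")
  # identical groups: t = 0, p = 1
  t13 <- d[d$comparison == "T1vT3", ]
  expect_equal(t13$t_statistic, 0)
  expect_equal(t13$p_value, 1)
  expect_false(t13$significant)
})

test_that("swapping group labels flips t and preserves p", {
  set.seed(42)
  runs <- data.frame(run_id = paste0("r", 1:9), tissue = "cement",
                     extraction = "SDS",
                     time = rep(c("T1", "T2", "T3"), each = 3),
                     bio_rep = 1, tech_rep = 1:3)
  v <- matrix(rlnorm(45, 10, 1), nrow = 5,
              dimnames = list(paste0("p", 1:5), runs$run_id))
  q <- quant_matrix(v, runs)
  d <- differential_test(q)
  # swap the T1 and T2 labels
  runs2 <- runs
  runs2$time <- c("T2", "T2", "T2", "T1", "T1", "T1", "T3", "T3", "T3")
  d2 <- differential_test(quant_matrix(v, runs2))
  a <- d[d$comparison == "T1vT2", ]
  b <- d2[d2$comparison == "T1vT2", ]
  expect_equal(b$t_statistic, -a$t_statistic)
  expect_equal(b$p_value, a$p_value)
})

test_that("type-I error and p-value uniformity hold under the null", {
  set.seed(202)
  n <- 1000
  runs <- data.frame(run_id = paste0("r", 1:18), tissue = "cement",
                     extraction = "SDS",
                     time = rep(c("T1", "T2", "T3"), each = 6),
                     bio_rep = rep(rep(1:2, each = 3), 3),
                     tech_rep = rep(1:3, 6))
  v <- matrix(rlnorm(n * 18, 10, 0.3), nrow = n,
              dimnames = list(paste0("p", 1:n), runs$run_id))
  d <- differential_test(quant_matrix(v, runs))
  p12 <- d$p_value[d$comparison == "T1vT2"]
  rate <- mean(p12 < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  ks <- suppressWarnings(ks.test(p12, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bio_rep_mean averages technical replicates before testing", {
  runs <- data.frame(run_id = paste0("r", 1:12), tissue = "cement",
                     extraction = "SDS",
                     time = rep(c("T1", "T2", "T3"), each = 4),
                     bio_rep = rep(rep(1:2, each = 2), 3),
                     tech_rep = rep(1:2, 6))
  v <- matrix(c(1, 3, 5, 7,   10, 12, 14, 16,  1, 1, 1, 1), nrow = 1,
              dimnames = list("p1", runs$run_id))
  d <- differential_test(quant_matrix(v, runs),
                         replicate_unit = "bio_rep_mean")
  t12 <- d[d$comparison == "T1vT2", ]
  # bio means: T1 {2, 6}, T2 {11, 15}: diff -9, pooled sd 2*sqrt(2)... se 4? no:
  # var each group = 8, se = sqrt(8 * (1/2 + 1/2)) = 2.828; t = -9/2.828
  expect_equal(t12$mean_a, 4)
  expect_equal(t12$mean_b, 13)
  expect_equal(t12$t_statistic, -9 / sqrt(8), tolerance = 1e-9)
  expect_equal(t12$df, 2)
})

test_that("untestable groups are flagged rather than dropped", {
  runs <- data.frame(run_id = paste0("r", 1:5), tissue = "cement",
                     extraction = "SDS",
                     time = c("T1", "T1", "T2", "T2", "T3"),
                     bio_rep = 1, tech_rep = c(1, 2, 1, 2, 1))
  v <- matrix(1:5, nrow = 1, dimnames = list("p1", runs$run_id))
  d <- differential_test(quant_matrix(v, runs))
  expect_false(d$untestable[d$comparison == "T1vT2"])
  expect_true(all(d$untestable[d$comparison %in% c("T2vT3", "T1vT3")]))
  expect_true(all(is.na(d$p_value[d$untestable])))
  expect_false(any(d$significant[d$untestable]))
})

test_that("one-way ANOVA matches explicit sums of squares", {
  # groups [1,2,3],[2,3,4],[3,4,5]: SSB = 6, SSW = 6, df (2, 6), F = 3
  res <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3)
  expect_equal(res$p, 0.125, tolerance = 1e-9)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  # cross-check against the stats reference implementation
  ref <- oneway.test(y ~ g,
                     data = data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                                       g = factor(rep(1:3, each = 3))),
                     var.equal = TRUE)
  expect_equal(res$F, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # degenerate cases
  same <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  sep <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_error(anova_oneway(list(c(1, 2))), "2 groups")
  expect_error(anova_oneway(list(1, c(1, 2))), "at least 2 values")
})

test_that("ANOVA type-I error is nominal under the null", {
  set.seed(33)
  p <- replicate(1000, {
    anova_oneway(list(rnorm(4), rnorm(4), rnorm(4)))$p
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})
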