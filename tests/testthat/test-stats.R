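test_that("balanced designs with equal cell means give F = 0", {
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:4) |>
    dplyr::mutate(value = rep(c(1, -1), times = 8))
  # every cell holds the same values {1,-1}: all means equal
  res <- tidy(two_way_anova(d, value, a, b))
  expect_equal(res$statistic, rep(0, 3), tolerance = 1e-10)
  expect_equal(res$p.value, rep(1, 3), tolerance = 1e-10)
})

test_that("two-way F values match a hand-computed decomposition", {
  # balanced 2x3, n = 2 per cell: closed-form Type-III == classical SS
  d <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                          rep = 1:2)
  d$value <- c(3, 5, 1, 3, 2, 6, 7, 9, 2, 4, 8, 10)
  res <- tidy(two_way_anova(d, value, a, b))

  # independent decomposition from cell means
  n <- 2
  gm <- mean(d$value)
  am <- tapply(d$value, d$a, mean)
  bm <- tapply(d$value, d$b, mean)
  cm <- tapply(d$value, list(d$a, d$b), mean)
  ss_a <- n * 3 * sum((am - gm)^2)
  ss_b <- n * 2 * sum((bm - gm)^2)
  ss_ab <- n * sum((cm - outer(am - gm, bm - gm, `+`) - gm)^2)
  ss_e <- sum((d$value - cm[cbind(d$a, d$b)])^2)
  ms_e <- ss_e / (12 - 6)
  expect_equal(res$sumsq, c(ss_a, ss_b, ss_ab), tolerance = 1e-9)
  expect_equal(res$statistic,
               c(ss_a / 1, ss_b / 2, ss_ab / 2) / ms_e, tolerance = 1e-9)
  expect_equal(res$df, c(1, 2, 2))
  expect_equal(res$df_resid, rep(6, 3))
})

test_that("two-way design errors name the offending cell", {
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3) |>
    dplyr::mutate(value = rnorm(12))
  empty <- dplyr::filter(d, !(a == "y" & b == "v"))
  expect_error(two_way_anova(empty, value, a, b), "empty design cell: y x v")
  single <- dplyr::filter(d, !(a == "y" & b == "v" & rep > 1))
  expect_error(two_way_anova(single, value, a, b), "n = 1")
  one_level <- dplyr::filter(d, a == "x")
  expect_error(two_way_anova(one_level, value, a, b), "2 levels")
})

test_that("one-way ANOVA on two groups is the squared pooled t", {
  set.seed(21)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 12),
                      value = rnorm(24, mean = rep(c(0, 1), each = 12)))
  f <- tidy(one_way_anova(d, value, g))$statistic
  tt <- t.test(value ~ g, data = d, var.equal = TRUE)$statistic
  expect_equal(f, unname(tt)^2, tolerance = 1e-9)
})

test_that("identical groups give F = 0 and Tukey p = 1", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 6),
                      value = rep(c(2, 4, 6, 1, 3, 5), 2))
  expect_equal(tidy(one_way_anova(d, value, g))$statistic, 0,
               tolerance = 1e-9)
  tk <- tidy(tukey_hsd(d, value, g))
  expect_equal(tk$adj.p.value, 1, tolerance = 1e-9)
  expect_equal(tk$estimate, 0, tolerance = 1e-12)
})

test_that("Tukey adjusted p matches the studentized-range computation", {
  set.seed(9)
  k <- 3; n <- 8
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = n),
                      value = rnorm(k * n, rep(c(0, 0.5, 2), each = n)))
  tk <- tidy(tukey_hsd(d, value, g))
  fit <- aov(value ~ g, data = d)
  mse <- sum(fit$residuals^2) / fit$df.residual
  means <- tapply(d$value, d$g, mean)
  pairs <- t(combn(names(means), 2))
  for (r in seq_len(nrow(pairs))) {
    q_obs <- abs(means[pairs[r, 2]] - means[pairs[r, 1]]) / sqrt(mse / n)
    p_exp <- ptukey(q_obs, nmeans = k, df = fit$df.residual,
                    lower.tail = FALSE)
    contrast <- paste(pairs[r, 2], pairs[r, 1], sep = "-")
    expect_equal(unname(tk$adj.p.value[tk$contrast == contrast]),
                 unname(p_exp), tolerance = 1e-6)
  }
  # adjusted p never below the unadjusted p of the same comparison
  for (r in seq_len(nrow(pairs))) {
    q_obs <- abs(means[pairs[r, 2]] - means[pairs[r, 1]]) / sqrt(mse / n)
    p_unadj <- 2 * pt(-q_obs / sqrt(2), df = fit$df.residual)
    contrast <- paste(pairs[r, 2], pairs[r, 1], sep = "-")
    expect_gte(tk$adj.p.value[tk$contrast == contrast] + 1e-12, p_unadj)
  }
})

test_that("group separation is detected only where it exists", {
  set.seed(4)
  reps <- 200
  hits <- replicate(reps, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 20),
                        value = rnorm(60, rep(c(0, 0, 5), each = 20)))
    tk <- tidy(tukey_hsd(d, value, g))
    sig <- tk$contrast[tk$adj.p.value < 0.05]
    setequal(sig, c("c-a", "c-b"))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("per-step Tukey families run within each step", {
  set.seed(6)
  d <- tidyr::expand_grid(g = c("a", "b"), step = c(10, 20), rep = 1:6) |>
    dplyr::mutate(value = rnorm(dplyr::n()) + ifelse(g == "b" & step == 20, 3, 0))
  tb <- tukey_by_step(d, value, g, step)
  expect_setequal(unique(tb$step), c(10, 20))
  expect_lt(tb$adj.p.value[tb$step == 20], 0.05)
  expect_gt(tb$adj.p.value[tb$step == 10], 0.05)
})

test_that("group summaries report mean, SEM and n", {
  d <- tibble::tibble(g = c("a", "a", "a", "b"),
                      value = c(1, 2, 3, 7))
  s <- summarize_groups(d, value, g)
  expect_equal(s$mean, c(2, 7))
  expect_equal(s$sem[1], 1 / sqrt(3))
  expect_true(is.na(s$sem[2]))  # single observation: SEM undefined
  expect_equal(s$n, c(3L, 1L))
  set.seed(2)
  r <- tibble::tibble(g = rep("x", 50), value = rnorm(50))
  s2 <- summarize_groups(r, value, g)
  expect_equal(s2$sem, sd(r$value) / sqrt(50))
})

test_that("anova objects expose tidy and glance metadata", {
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3) |>
    dplyr::mutate(value = rnorm(12))
  res <- two_way_anova(d, value, a, b)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n, 12)
  expect_equal(g$n_cells, 4)
  expect_equal(g$min_cell_n, 3)
})
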