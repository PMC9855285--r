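
test_that("independent t reproduces printed-summary statistics exactly", {
  res <- independent_t(list(mean = 2.66, sd = 1.005, n = 18),
                       list(mean = 2.42, sd = 0.688, n = 18))
  expect_equal(res$statistic, 0.836, tolerance = 0.005 / 0.836)
  expect_equal(res$effect_size, 0.279, tolerance = 0.005 / 0.279)
  expect_equal(res$df1, 34)

  # raw-data and summary entry points agree exactly
  set.seed(2)
  x <- rnorm(18, 2.66, 1); y <- rnorm(18, 2.42, 0.7)
  raw <- independent_t(x, y)
  summ <- independent_t(list(mean = mean(x), sd = sd(x), n = 18),
                        list(mean = mean(y), sd = sd(y), n = 18))
  expect_identical(raw$statistic, summ$statistic)
  # and match stats::t.test with pooled variance
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$p, tt$p.value, tolerance = 1e-12)

  expect_error(independent_t(rep(1, 5), rep(1, 4)), "pooled variance")
})

test_that("paired t equals the one-sample t on differences", {
  set.seed(3)
  x <- rnorm(18); y <- x + rnorm(18, 0.3)
  res <- paired_t(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df1, 17)
  expect_equal(res$effect_size, mean(x - y) / sd(x - y))
  expect_equal(paired_t(x, y, d_method = "pooled")$effect_size,
               mean(x - y) / sqrt((var(x) + var(y)) / 2))
  expect_error(paired_t(1:3, 1:3 + 1), "zero difference variance")
})

test_that("pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_r(1:10, 1:10)$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  res <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$statistic, r_hand, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
})

test_that("JZS Bayes factors match a g-prior quadrature oracle and are coherent", {
  # oracle: Rouder-style integral over g with inverse-gamma(1/2, r^2/2) prior
  bf_g <- function(t, n1, n2, r = sqrt(2) / 2) {
    neff <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
    num <- integrate(function(g)
      (1 + neff * g * r^2)^(-1 / 2) *
        (1 + t^2 / (nu * (1 + neff * g * r^2)))^(-(nu + 1) / 2) *
        (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g)),
      0, Inf, rel.tol = 1e-10)$value
    num / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  for (t in c(0, 0.836, 2.5)) {
    expect_equal(jzs_bf_ttest(t, 18, 18), bf_g(t, 18, 18),
                 tolerance = 1e-5)
  }
  # t = 0 favors the null for any n; |t| increase raises BF10
  expect_lt(jzs_bf_ttest(0, 18, 18), 1)
  expect_lt(jzs_bf_ttest(0, 5), 1)
  bfs <- vapply(c(0.5, 1, 2, 3, 5), jzs_bf_ttest, 0, n1 = 18, n2 = 18)
  expect_true(all(diff(bfs) > 0))
  expect_gt(jzs_bf_ttest(8, 18, 18), 1000)
})

test_that("mixed ANOVA matches the sums-of-squares oracle on random designs", {
  for (rep in 1:5) {
    set.seed(100 + rep)
    n <- c(8, 12, 18)[(rep %% 3) + 1]
    Y <- matrix(rnorm(2 * n * 3, mean = rep(c(0, 0.3, -0.2), each = 2 * n)),
                2 * n, 3)
    colnames(Y) <- cda_conditions
    grp <- rep(c("depressed", "control"), each = n)
    res <- rm_anova_mixed(Y, grp)
    orc <- ss_oracle(Y, grp)
    expect_equal(res$statistic[res$effect == "group"], orc$F_group,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "condition"], orc$F_cond,
                 tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "condition:group"], orc$F_int,
                 tolerance = 1e-8)
  }
})

test_that("ANOVA and ANCOVA report the design degrees of freedom", {
  set.seed(9)
  Y <- matrix(rnorm(36 * 3), 36, 3, dimnames = list(NULL, cda_conditions))
  grp <- rep(c("depressed", "control"), each = 18)
  res <- rm_anova_mixed(Y, grp)
  expect_equal(res[res$effect == "condition", c("df1", "df2")],
               data.frame(df1 = 2, df2 = 68), ignore_attr = TRUE)
  expect_equal(res[res$effect == "group", c("df1", "df2")],
               data.frame(df1 = 1, df2 = 34), ignore_attr = TRUE)

  k <- rnorm(36)
  anc <- ancova_mixed(Y, grp, k)
  expect_equal(anc[anc$effect == "condition:group", c("df1", "df2")],
               data.frame(df1 = 2, df2 = 66), ignore_attr = TRUE)

  # degenerate inputs
  expect_error(rm_anova_mixed(Y[, 1, drop = FALSE], grp), "2 within")
  Yna <- Y; Yna[3, 2] <- NA
  expect_error(rm_anova_mixed(Yna, grp), "missing cells")
  expect_error(ancova_mixed(Y, grp, rep(1, 36)), "constant covariate")
  expect_error(ancova_mixed(Y, grp, as.numeric(grp == "control")),
               "confounded")
  all_same <- matrix(2, 36, 3, dimnames = list(NULL, cda_conditions))
  res0 <- rm_anova_mixed(all_same, grp)
  expect_true(all(res0$statistic == 0))
})

test_that("ANCOVA with an orthogonalized covariate rescales the interaction F", {
  set.seed(11)
  Y <- matrix(rnorm(36 * 3), 36, 3, dimnames = list(NULL, cda_conditions))
  grp <- rep(c("depressed", "control"), each = 18)
  z <- rnorm(36)
  # residualize z against intercept, group and every condition column
  z_orth <- residuals(lm(z ~ grp + Y))
  res_a <- rm_anova_mixed(Y, grp)
  res_c <- ancova_mixed(Y, grp, z_orth)
  Fa <- res_a$statistic[res_a$effect == "condition:group"]
  Fc <- res_c$statistic[res_c$effect == "condition:group"]
  # same interaction and error SS, one within df transferred to the covariate
  expect_equal(Fc, Fa * 66 / 68, tolerance = 1e-8)
})
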