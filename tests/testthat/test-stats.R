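# stats module: agreement and nonparametric battery against hand oracles
# and base-R references.

test_that("bland_altman matches hand-computed bias and limits", {
  x <- c(10, 12, 11, 14, 13, 15)
  y <- c(9, 13, 10, 15, 12, 14)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$n, 6L)
  expect_error(bland_altman(1:5, 1:4), "paired")
  expect_error(bland_altman(c(1, NA, 3), c(1, 2, 3)), "finite")
  expect_error(bland_altman(1:2, 2:3), "3 pairs")
})

test_that("bland_altman handles identical measurements gracefully", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$pct_outside, 0)
  expect_equal(ba$loa_low, ba$loa_high)
})

test_that("lin_ccc matches its closed form and penalizes shifts", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lin_ccc(x, x), 1)
  # constant shift: ccc = 2*var / (2*var + shift^2) with population moments
  y <- x + 2
  v <- mean((x - mean(x))^2)
  expect_equal(lin_ccc(x, y), 2 * v / (2 * v + 4))
  expect_equal(lin_ccc(x, rev(x)), -1)
  expect_lt(lin_ccc(x, 2 * x), 1)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 1, 1)), "zero")
})

test_that("spearman_cor matches stats::cor and its t approximation", {
  set.seed(51)
  x <- rnorm(30); y <- x + rnorm(30)
  s <- spearman_cor(x, y)
  expect_equal(s$rho, cor(x, y, method = "spearman"))
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(s$p_value, unname(ref$p.value), tolerance = 1e-8)
  # mid-ranks on ties
  xt <- c(1, 2, 2, 3, 4, 5); yt <- c(2, 1, 3, 3, 5, 6)
  expect_equal(spearman_cor(xt, yt)$rho, cor(xt, yt, method = "spearman"))
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "4 complete pairs")
})

test_that("kruskal_dunn reproduces the hand example H = 7.2", {
  kd <- kruskal_dunn(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kd$statistic, 7.2)
  expect_equal(kd$df, 2)
  expect_equal(kd$p_value, pchisq(7.2, 2, lower.tail = FALSE))
})

test_that("kruskal_dunn H agrees with the rank formula and kruskal.test", {
  set.seed(52)
  v <- rnorm(40); g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  kd <- kruskal_dunn(v, g)
  expect_equal(kd$statistic, oracle_kw_h(v, g))
  ref <- kruskal.test(v, factor(g))
  expect_equal(kd$statistic, unname(ref$statistic))
  expect_equal(kd$p_value, ref$p.value)
  # Dunn table covers all pairs with Holm-monotone adjusted p-values
  expect_equal(nrow(kd$posthoc), 3L)
  expect_true(all(kd$posthoc$p_adjusted >= kd$posthoc$p_value))
  raw <- kruskal_dunn(v, g, p_adjust = "none")
  expect_equal(raw$posthoc$p_value, raw$posthoc$p_adjusted)
})

test_that("kruskal_dunn handles ties and degenerate input", {
  v <- c(1, 1, 2, 2, 3, 3, 4, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(kruskal_dunn(v, g)$statistic,
               unname(kruskal.test(v, factor(g))$statistic))
  allsame <- kruskal_dunn(rep(7, 9), g)
  expect_equal(allsame$statistic, 0)
  expect_equal(allsame$p_value, 1)
  expect_error(kruskal_dunn(1:5, rep("a", 5)), "two groups")
  expect_error(kruskal_dunn(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})

test_that("wilcoxon_paired matches exact enumeration for n <= 10", {
  set.seed(53)
  for (rep_i in 1:10) {
    n <- sample(6:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    w <- wilcoxon_paired(x, y)
    expect_true(w$exact)
    expect_equal(w$p_value, oracle_signed_rank_p(x - y),
                 label = sprintf("replicate %d", rep_i))
  }
})

test_that("wilcoxon_paired matches stats::wilcox.test", {
  set.seed(54)
  x <- rnorm(20); y <- rnorm(20)
  w <- wilcoxon_paired(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_value, ref$p.value)
  # tied differences force the corrected normal approximation
  xt <- c(1, 2, 3, 4, 5, 6, 8, 9)
  yt <- c(2, 1, 5, 2, 8, 3, 5, 4)
  wt <- wilcoxon_paired(xt, yt)
  expect_false(wt$exact)
  rt <- wilcox.test(xt, yt, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(wt$p_value, rt$p.value)
})

test_that("wilcoxon_paired handles zeros and degenerate input", {
  expect_warning(w0 <- wilcoxon_paired(rep(1, 6), rep(1, 6)), "degenerate")
  expect_equal(w0$p_value, 1)
  expect_error(wilcoxon_paired(c(1, 1, 1, 1, 2), c(1, 1, 1, 1, 1)),
               "5 non-zero")
})

test_that("scheirer_ray_hare collapses to Kruskal-Wallis for one factor_b level", {
  set.seed(55)
  v <- sample(1000, 30)  # untied
  g <- rep(c("a", "b", "c"), each = 10)
  srh <- scheirer_ray_hare(v, g, rep("only", 30))
  expect_equal(nrow(srh), 1L)
  expect_equal(srh$H, kruskal_dunn(v, g)$statistic)
  expect_equal(srh$df, 2L)
})

test_that("scheirer_ray_hare decomposes rank SS additively on balanced data", {
  set.seed(56)
  a <- rep(c("g1", "g2", "g3"), each = 8)
  b <- rep(rep(c("young", "old"), each = 4), 3)
  v <- rnorm(24) + (a == "g3") * 2
  srh <- scheirer_ray_hare(v, a, b)
  expect_equal(srh$term, c("factor_a", "factor_b", "interaction"))
  expect_equal(srh$df, c(2L, 1L, 2L))
  # balanced design: effect H statistics are the sequential rank SS over
  # MS_total, and all chi-square p-values are in (0, 1]
  r <- rank(v)
  ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
  ss_a <- sum(tapply(r, a, function(z) length(z) * (mean(z) - mean(r))^2))
  ss_b <- sum(tapply(r, b, function(z) length(z) * (mean(z) - mean(r))^2))
  cellm <- tapply(r, list(a, b), mean)
  ss_cells <- sum(4 * (cellm - mean(r))^2)
  expect_equal(srh$H[1], ss_a / ms_total)
  expect_equal(srh$H[2], ss_b / ms_total)
  expect_equal(srh$H[3], (ss_cells - ss_a - ss_b) / ms_total)
  expect_equal(srh$p_value, pchisq(srh$H, srh$df, lower.tail = FALSE))
  expect_true(all(srh$partial_eta2 >= 0 & srh$partial_eta2 <= 100))
})

test_that("scheirer_ray_hare rejects empty cells and degenerate designs", {
  a <- rep(c("g1", "g2"), each = 6)
  b <- c(rep("x", 6), rep("y", 6))  # cell (g1, y) and (g2, x) empty
  expect_error(scheirer_ray_hare(rnorm(12), a, b), "empty design cells")
  expect_error(scheirer_ray_hare(rnorm(6), rep("a", 6), rep(c("x", "y"), 3)),
               "factor_a")
  const <- scheirer_ray_hare(rep(3, 24), rep(c("a", "b", "c"), each = 8),
                             rep(c("x", "y"), 12))
  expect_true(all(const$H == 0) && all(const$p_value == 1))
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(57)
  v <- rlnorm(36)
  a <- rep(c("g1", "g2", "g3"), each = 12)
  b <- rep(rep(c("x", "y"), each = 6), 3)
  x <- rnorm(20); y <- rnorm(20)
  for (f in list(function(z) z, exp, function(z) z^3, function(z) -1 / (1 + pmax(z, 0)))) {
    expect_equal(kruskal_dunn(f(v), a)$statistic, kruskal_dunn(v, a)$statistic)
    expect_equal(scheirer_ray_hare(f(v), a, b)$H, scheirer_ray_hare(v, a, b)$H)
    expect_equal(spearman_cor(f(v), v)$rho, 1)
  }
  # Spearman rho invariant under strictly increasing transforms of either side
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
})

test_that("shapiro_gate delegates to shapiro.test and gates correctly", {
  set.seed(58)
  xn <- rnorm(50)
  g <- shapiro_gate(xn)
  ref <- shapiro.test(xn)
  expect_equal(g$W, unname(ref$statistic))
  expect_equal(g$p_value, ref$p.value)
  xs <- rexp(200)^3
  expect_true(shapiro_gate(xs)$use_nonparametric)
  expect_error(shapiro_gate(c(1, 2)), "3 <= n")
  expect_error(shapiro_gate(rep(1, 10)), "constant")
})

test_that("run_study_analysis assembles the full battery on a cohort table", {
  set.seed(59)
  n <- 47
  groups <- rep(CRANIAL_GROUPS, c(17, 17, 13))
  age <- sample(18:78, n, replace = TRUE)
  psi_b <- ifelse(groups == "CRANIECTOMY", 3.3, 2.0) + rnorm(n, 0, 0.25)
  tab <- rbind(
    data.frame(patient_id = sprintf("P%02d", 1:n), age = age,
               cranial_group = groups, phase = "baseline",
               psi_icp = psi_b, psi_b4c = psi_b + rnorm(n, 0, 0.15),
               mean_icp = rnorm(n, 11.8, 1.5)),
    data.frame(patient_id = sprintf("P%02d", 1:n), age = age,
               cranial_group = groups, phase = "compression",
               psi_icp = psi_b + 0.2, psi_b4c = psi_b + 0.2 + rnorm(n, 0, 0.15),
               mean_icp = rnorm(n, 17.1, 1.5)))
  rep_ <- run_study_analysis(tab)
  expect_s3_class(rep_, "psi_study_report")
  expect_named(rep_$agreement$baseline, c("bland_altman", "ccc", "spearman"))
  expect_true(rep_$agreement$baseline$ccc > 0.5)
  expect_equal(rep_$group_effect$icp$df, 2)
  expect_lt(rep_$group_effect$icp$p_value, 0.01)  # built-in group separation
  expect_equal(sort(rep_$factorial$icp$term),
               sort(c("factor_a", "factor_b", "interaction")))
  expect_lt(rep_$compression_effect$icp$pooled$p_value, 0.01)
  expect_equal(rep_$compression_effect$mean_icp$baseline$n, n)
  expect_length(rep_$gaps, 0)
  expect_error(run_study_analysis(tab[, -5]), "columns")
})
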