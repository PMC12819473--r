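# Method-agreement and nonparametric group-comparison statistics.
#
# The battery applied to the cohort table: Bland-Altman limits of agreement,
# Lin's concordance correlation, Spearman rank correlation, Kruskal-Wallis
# with Dunn post hoc comparisons, the Wilcoxon signed-rank test, a
# Shapiro-Wilk normality gate, and the Scheirer-Ray-Hare rank-based two-way
# factorial analysis with partial eta-squared effect sizes.

#' Bland-Altman agreement analysis
#'
#' For paired measurements the differences `d = x - y` give the bias
#' (mean difference) and the limits of agreement `bias +/- 1.96 * sd(d)`
#' (sample standard deviation, denominator n - 1), together with the
#' percentage of pairs falling outside the limits.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return List of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `pct_outside`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must be paired")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stopf("`x` and `y` must be pairwise finite")
  n <- length(x)
  if (n < 3L) stopf("at least 3 pairs are required")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0) {
    return(structure(list(bias = bias, loa_low = bias, loa_high = bias,
                          sd_diff = 0, pct_outside = 0, n = n),
                     class = "bland_altman"))
  }
  loa <- bias + c(-1.96, 1.96) * sdd
  pct <- 100 * mean(abs(d - bias) > 1.96 * sdd)
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 sd_diff = sdd, pct_outside = pct, n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f], %.1f%% outside\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$pct_outside))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` using
#' population (n-denominator) moments. Penalizes both dispersion and
#' location shifts; reduces to the Pearson correlation when the two
#' measurements share means and variances.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return A number in \[-1, 1\].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must be paired")
  n <- length(x)
  if (n < 3L) stopf("at least 3 pairs are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("inputs must be finite")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom <= 0) stopf("concordance undefined: total variance is zero")
  2 * cxy / denom
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with the
#' p-value from the large-sample t approximation on n - 2 degrees of
#' freedom.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stopf("at least 4 complete pairs are required")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stopf("Spearman correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(rho = rho, p_value = min(1, p), n = n)
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' The tie-corrected H statistic is referred to chi-square on k - 1 degrees
#' of freedom (delegated to [stats::kruskal.test()]). Dunn's pairwise
#' z-statistics are computed on the pooled mid-ranks with the tie
#' correction `sum(t^3 - t) / (12 (N - 1))` in the standard error, and are
#' Holm-adjusted by default.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (>= 2 groups, each of size >= 2).
#' @param p_adjust Adjustment for the Dunn p-values: any method of
#'   [stats::p.adjust()] (default `"holm"`) or `"none"`.
#' @return List of class `kruskal_dunn`: `statistic` (H), `df`, `p_value`,
#'   `n`, and `posthoc`, a data frame of pairwise comparisons.
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stopf("at least two groups are required")
  sizes <- table(groups)
  if (any(sizes < 2L)) stopf("every group needs n >= 2 (got %s)",
                             paste(sizes, collapse = ", "))
  N <- length(values)
  if (diff(range(values)) == 0) {
    H <- 0; p <- 1; df <- k - 1L
  } else {
    kt <- stats::kruskal.test(values, groups)
    H <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
  }
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(levels(groups), 2L)
  ph <- data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
                   stringsAsFactors = FALSE)
  ph$z <- mapply(function(a, b) {
    se <- sqrt(s2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
  }, ph$group1, ph$group2)
  ph$p_value <- 2 * stats::pnorm(-abs(ph$z))
  ph$p_adjusted <- if (identical(p_adjust, "none")) ph$p_value else
    stats::p.adjust(ph$p_value, method = p_adjust)
  structure(list(statistic = H, df = df, p_value = p, n = N, posthoc = ph,
                 p_adjust = p_adjust),
            class = "kruskal_dunn")
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; at least 5 non-zero differences are
#' required. Ties receive mid-ranks. The exact null distribution is used
#' when there are no ties among the absolute differences and n <= 50;
#' otherwise the normal approximation with continuity and tie correction.
#' When every difference is zero the test is degenerate and returns p = 1
#' with a warning.
#'
#' @param x,y Paired numeric vectors.
#' @return List of class `wilcoxon_paired`: `statistic` (V, the positive
#'   rank sum), `p_value`, `n` (non-zero differences), `exact`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must be paired")
  d <- x - y
  d <- d[is.finite(d)]
  if (!length(d)) stopf("no finite differences")
  if (all(d == 0)) {
    warnf("all differences are zero; test is degenerate")
    return(structure(list(statistic = 0, p_value = 1, n = 0L, exact = FALSE),
                     class = "wilcoxon_paired"))
  }
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stopf("at least 5 non-zero differences are required")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 50L) {
    mid <- n * (n + 1) / 4
    p <- if (V > mid) 2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
         else 2 * stats::psignrank(V, n)
    p <- min(1, p)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = V, p_value = p, n = n, exact = exact),
            class = "wilcoxon_paired")
}

#' Scheirer-Ray-Hare rank-based two-way factorial analysis
#'
#' All values are ranked jointly (mid-ranks on ties) and a two-way factorial
#' decomposition of the rank sums of squares is formed. H statistics are
#' `SS_effect / MS_total` with `MS_total = SS_total / (n - 1)`, referred to
#' chi-square on the effect's degrees of freedom. Unbalanced designs are
#' handled by marginal (Type II) sums of squares, which coincide with the
#' sequential decomposition on balanced data. Partial eta-squared is
#' `100 * SS_effect / (SS_effect + SS_error)`.
#'
#' When `factor_b` has a single level the analysis collapses to a one-way
#' rank decomposition whose H equals the (untied) Kruskal-Wallis statistic.
#'
#' @param values Numeric response vector.
#' @param factor_a First factor (2-3 levels typical).
#' @param factor_b Second factor.
#' @return Data frame of class `scheirer_ray_hare` with rows for
#'   `factor_a`, `factor_b` and `interaction`: `H`, `df`, `p_value`,
#'   `partial_eta2` (percent).
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  ok <- is.finite(values) & !is.na(a) & !is.na(b)
  values <- values[ok]; a <- droplevels(a[ok]); b <- droplevels(b[ok])
  n <- length(values)
  if (nlevels(a) < 2L) stopf("`factor_a` needs at least 2 levels")
  n_cells <- nlevels(a) * max(1L, nlevels(b))
  if (n < n_cells + 2L) stopf("too few observations for the design")
  if (nlevels(b) > 1L) {
    cells <- table(a, b)
    if (any(cells == 0L)) {
      empty <- which(cells == 0L, arr.ind = TRUE)
      stopf("empty design cells: %s",
            paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                          colnames(cells)[empty[, 2]]), collapse = ", "))
    }
  }
  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) {
    dfs <- c(nlevels(a) - 1L,
             if (nlevels(b) > 1L) nlevels(b) - 1L else NA_integer_,
             if (nlevels(b) > 1L) (nlevels(a) - 1L) * (nlevels(b) - 1L) else NA_integer_)
    out <- data.frame(term = c("factor_a", "factor_b", "interaction"),
                      H = c(0, 0, 0), df = dfs, p_value = c(1, 1, 1),
                      partial_eta2 = c(0, 0, 0))
    out <- out[!is.na(out$df), , drop = FALSE]
    class(out) <- c("scheirer_ray_hare", "data.frame")
    return(out)
  }
  rss <- function(mm) sum(stats::lsfit(mm, r, intercept = FALSE)$residuals^2)
  ms_total <- ss_total / (n - 1)
  if (nlevels(b) < 2L) {
    mm_a <- stats::model.matrix(~a)
    ss_a <- sum((r - mean(r))^2) - rss(mm_a)
    ss_err <- rss(mm_a)
    out <- data.frame(term = "factor_a", H = ss_a / ms_total,
                      df = nlevels(a) - 1L,
                      p_value = stats::pchisq(ss_a / ms_total,
                                              nlevels(a) - 1L, lower.tail = FALSE),
                      partial_eta2 = 100 * ss_a / (ss_a + ss_err))
    class(out) <- c("scheirer_ray_hare", "data.frame")
    return(out)
  }
  mm_a <- stats::model.matrix(~a)
  mm_b <- stats::model.matrix(~b)
  mm_ab <- stats::model.matrix(~a + b)
  mm_full <- stats::model.matrix(~a * b)
  rss_a <- rss(mm_a); rss_b <- rss(mm_b)
  rss_add <- rss(mm_ab); rss_full <- rss(mm_full)
  ss <- c(factor_a = rss_b - rss_add,
          factor_b = rss_a - rss_add,
          interaction = rss_add - rss_full)
  ss <- pmax(ss, 0)
  ss_err <- rss_full
  dfs <- c(nlevels(a) - 1L, nlevels(b) - 1L,
           (nlevels(a) - 1L) * (nlevels(b) - 1L))
  H <- ss / ms_total
  out <- data.frame(term = names(ss), H = unname(H), df = dfs,
                    p_value = stats::pchisq(unname(H), dfs, lower.tail = FALSE),
                    partial_eta2 = 100 * unname(ss) / (unname(ss) + ss_err))
  rownames(out) <- NULL
  class(out) <- c("scheirer_ray_hare", "data.frame")
  out
}

#' Shapiro-Wilk normality gate
#'
#' Standard Shapiro-Wilk test (delegated to [stats::shapiro.test()]); the
#' gate recommends nonparametric methods when p < `alpha`.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha Gate level (default 0.05).
#' @return List: `W`, `p_value`, `use_nonparametric`.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) stopf("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(x)) == 0) stopf("sample is constant; normality test undefined")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       use_nonparametric = sw$p.value < alpha)
}

#' Run the full study analysis on a cohort table
#'
#' Applies the complete statistical battery to a per-patient, per-phase
#' cohort table: per-phase agreement between the invasive and noninvasive
#' PSI (Bland-Altman, Lin's CCC, Spearman), Kruskal-Wallis with Dunn post
#' hoc tests across cranial groups per channel (baseline), Spearman
#' correlation of PSI with age per channel, the Scheirer-Ray-Hare analysis
#' of cranial group by age group (dichotomized at the cohort's own median
#' age) per channel, and Wilcoxon signed-rank comparisons of baseline versus
#' compression per channel, pooled and within groups. Group medians with
#' interquartile ranges are reported throughout. Missing phases or groups
#' yield a partial report with the gaps listed under `$gaps`.
#'
#' @param cohort Data frame with columns `patient_id`, `age`,
#'   `cranial_group`, `phase`, `psi_icp`, `psi_b4c`, `mean_icp` (one row per
#'   patient per phase).
#' @param p_adjust Dunn post hoc adjustment method.
#' @param alpha Level used by the normality gate.
#' @return Nested list of class `psi_study_report`.
#' @export
run_study_analysis <- function(cohort, p_adjust = "holm", alpha = 0.05) {
  need <- c("patient_id", "age", "cranial_group", "phase", "psi_icp",
            "psi_b4c", "mean_icp")
  if (!all(need %in% names(cohort)))
    stopf("cohort table needs columns: %s", paste(need, collapse = ", "))
  gaps <- character(0)
  phases <- intersect(c("baseline", "compression"), unique(cohort$phase))
  if (length(phases) < 2L)
    gaps <- c(gaps, sprintf("missing phase(s): %s",
                            paste(setdiff(c("baseline", "compression"),
                                          phases), collapse = ", ")))
  median_age <- stats::median(cohort$age[!duplicated(cohort$patient_id)])
  cohort$age_group <- ifelse(cohort$age <= median_age, "LE_MEDIAN", "GT_MEDIAN")

  report <- list(median_age = median_age, gaps = gaps)

  # method agreement per phase
  agreement <- list()
  for (ph in phases) {
    sub <- cohort[cohort$phase == ph & is.finite(cohort$psi_icp) &
                    is.finite(cohort$psi_b4c), ]
    if (nrow(sub) >= 4L) {
      agreement[[ph]] <- list(
        bland_altman = unclass(bland_altman(sub$psi_icp, sub$psi_b4c)),
        ccc = lin_ccc(sub$psi_icp, sub$psi_b4c),
        spearman = spearman_cor(sub$psi_icp, sub$psi_b4c))
    } else gaps <- c(gaps, sprintf("agreement (%s): too few pairs", ph))
  }
  pooled <- cohort[cohort$phase %in% phases & is.finite(cohort$psi_icp) &
                     is.finite(cohort$psi_b4c), ]
  if (nrow(pooled) >= 4L)
    agreement$pooled <- list(
      bland_altman = unclass(bland_altman(pooled$psi_icp, pooled$psi_b4c)),
      ccc = lin_ccc(pooled$psi_icp, pooled$psi_b4c))
  report$agreement <- agreement

  base <- cohort[cohort$phase == "baseline", ]
  channels <- c(icp = "psi_icp", b4c = "psi_b4c")
  groups_present <- unique(base$cranial_group)

  # descriptive medians (IQR) per group/phase/channel
  describe <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    list(median = stats::median(v), iqr = q[2] - q[1], n = length(v))
  }
  desc <- list()
  for (ph in phases) for (ch in names(channels)) {
    sub <- cohort[cohort$phase == ph, ]
    desc[[ph]][[ch]] <- list(
      pooled = describe(sub[[channels[[ch]]]]),
      by_group = lapply(split(sub[[channels[[ch]]]], sub$cranial_group),
                        describe))
  }
  report$descriptives <- desc

  # group effect (baseline), age effect, factorial analysis per channel
  group_tests <- list(); age_tests <- list(); srh_tests <- list()
  normality <- list()
  for (ch in names(channels)) {
    v <- base[[channels[[ch]]]]
    ok <- is.finite(v)
    normality[[ch]] <- tryCatch(shapiro_gate(v[ok], alpha = alpha),
                                error = function(e) NULL)
    if (length(groups_present) >= 2L && sum(ok) >= 6L) {
      group_tests[[ch]] <- tryCatch(
        unclass(kruskal_dunn(v[ok], base$cranial_group[ok], p_adjust = p_adjust)),
        error = function(e) { gaps <<- c(gaps, sprintf("group test (%s): %s", ch,
                                                       conditionMessage(e))); NULL })
    } else gaps <- c(gaps, sprintf("group test (%s): missing groups", ch))
    age_tests[[ch]] <- tryCatch(spearman_cor(base$age[ok], v[ok]),
                                error = function(e) NULL)
    srh_tests[[ch]] <- tryCatch(
      as.data.frame(scheirer_ray_hare(v[ok], base$cranial_group[ok],
                                      base$age_group[ok])),
      error = function(e) { gaps <<- c(gaps, sprintf("factorial (%s): %s", ch,
                                                     conditionMessage(e))); NULL })
  }
  report$normality <- normality
  report$group_effect <- group_tests
  report$age_effect <- age_tests
  report$factorial <- srh_tests

  # compression effect: baseline vs compression per channel, pooled & by group
  compression <- list()
  if (length(phases) == 2L) {
    wide <- merge(base[, c("patient_id", "cranial_group", channels, "mean_icp")],
                  cohort[cohort$phase == "compression",
                         c("patient_id", channels, "mean_icp")],
                  by = "patient_id", suffixes = c("_base", "_comp"))
    for (ch in names(channels)) {
      xb <- wide[[paste0(channels[[ch]], "_base")]]
      xc <- wide[[paste0(channels[[ch]], "_comp")]]
      ok <- is.finite(xb) & is.finite(xc)
      compression[[ch]]$pooled <- tryCatch(
        suppressWarnings(unclass(wilcoxon_paired(xb[ok], xc[ok]))),
        error = function(e) NULL)
      compression[[ch]]$by_group <- lapply(
        split(seq_len(nrow(wide))[ok], wide$cranial_group[ok]),
        function(idx) tryCatch(
          suppressWarnings(unclass(wilcoxon_paired(xb[idx], xc[idx]))),
          error = function(e) NULL))
    }
    okm <- is.finite(wide$mean_icp_base) & is.finite(wide$mean_icp_comp)
    compression$mean_icp <- list(
      baseline = describe(wide$mean_icp_base[okm]),
      compression = describe(wide$mean_icp_comp[okm]),
      test = tryCatch(
        suppressWarnings(unclass(wilcoxon_paired(wide$mean_icp_base[okm],
                                                 wide$mean_icp_comp[okm]))),
        error = function(e) NULL))
  }
  report$compression_effect <- compression
  report$gaps <- gaps
  class(report) <- "psi_study_report"
  report
}
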