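stat_result <- function(test, effect, statistic, df1, df2 = NA_real_, p,
                        effect_size = NA_real_, bf10 = NA_real_,
                        notes = "") {
  data.frame(test = test, effect = effect, statistic = statistic,
             df1 = df1, df2 = df2, p = p, effect_size = effect_size,
             bf10 = bf10, notes = notes, stringsAsFactors = FALSE)
}

as_summary <- function(x) {
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    stopifnot(x$n >= 2, x$sd >= 0)
    x
  } else {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("need at least 2 observations per group")
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
}

#' Independent-samples t test (pooled variance) with Cohen's d
#'
#' Student's two-sample t with pooled variance and `df = n1 + n2 - 2`.
#' Cohen's d is the mean difference divided by the pooled SD. Groups can be
#' given as raw vectors or as `list(mean =, sd =, n =)` summaries; both
#' entry points agree exactly when the summaries are computed from the raw
#' data, which also makes statistics reproducible from published summary
#' tables.
#'
#' @param x,y numeric vectors, or summary lists `list(mean, sd, n)`.
#' @param bf if `TRUE`, also compute the JZS default-prior Bayes factor.
#' @return A one-row `stat_result` data.frame (`statistic` = t,
#'   `effect_size` = Cohen's d).
#' @export
independent_t <- function(x, y, bf = FALSE) {
  a <- as_summary(x)
  b <- as_summary(y)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) stop("pooled variance is zero; t is undefined")
  df <- a$n + b$n - 2
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  d <- (a$mean - b$mean) / sqrt(sp2)
  p <- 2 * stats::pt(-abs(t), df)
  res <- stat_result("independent_t", "group", t, df, p = p,
                     effect_size = d)
  if (bf) res$bf10 <- jzs_bf_ttest(t, a$n, b$n)
  res
}

#' Paired-samples t test with Cohen's d
#'
#' One-sample t on the pairwise differences, `df = n - 1`. Because no
#' single Cohen's d convention is standard for paired designs, three are
#' available: `"dz"` (mean difference / SD of differences, the default),
#' `"dav"` (mean difference / average of the two condition SDs) and
#' `"pooled"` (mean difference / pooled condition SD).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param d_method Cohen's d convention.
#' @param bf if `TRUE`, also compute the JZS default-prior Bayes factor.
#' @return A one-row `stat_result` data.frame.
#' @export
paired_t <- function(x, y, d_method = c("dz", "dav", "pooled"), bf = FALSE) {
  d_method <- match.arg(d_method)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  di <- x - y
  sd_d <- stats::sd(di)
  if (sd_d == 0) stop("zero difference variance; t is undefined")
  n <- length(di)
  t <- mean(di) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  d <- switch(d_method,
              dz = mean(di) / sd_d,
              dav = mean(di) / ((stats::sd(x) + stats::sd(y)) / 2),
              pooled = mean(di) / sqrt((stats::var(x) + stats::var(y)) / 2))
  res <- stat_result("paired_t", "condition", t, n - 1, p = p,
                     effect_size = d, notes = paste0("d_", d_method))
  if (bf) res$bf10 <- jzs_bf_ttest(t, n)
  res
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A one-row `stat_result` data.frame (`statistic` = r, p from the
#'   t transform with `df = n - 2`).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  r <- stats::cor(x, y)
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  stat_result("pearson_r", "correlation", r, n - 2, p = p)
}

#' JZS default-prior Bayes factor for a t test
#'
#' Jeffreys-Zellner-Siow Bayes factor `BF10`: the marginal likelihood of
#' the observed t statistic under a Cauchy(0, `rscale`) prior on the
#' standardized effect size, divided by its likelihood under the point
#' null. Computed by adaptive quadrature of the noncentral-t density
#' against the Cauchy prior (relative tolerance 1e-8). Values below 1 favor
#' the null. The default prior width is the conventional sqrt(2)/2.
#'
#' @param t observed t statistic.
#' @param n1 first (or only, for paired/one-sample) sample size.
#' @param n2 second sample size for the two-sample test, or `NULL`.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return `BF10` (alternative/null odds), a positive scalar.
#' @export
jzs_bf_ttest <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  stopifnot(is.finite(t), n1 >= 2)
  if (is.null(n2)) {
    neff <- n1
    df <- n1 - 1
  } else {
    stopifnot(n2 >= 2)
    neff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  marg <- suppressWarnings(stats::integrate(
    function(delta) stats::dt(t, df, ncp = delta * sqrt(neff)) *
      stats::dcauchy(delta, 0, rscale),
    -Inf, Inf, rel.tol = 1e-8))
  if (marg$message != "OK" || marg$value <= 0)
    stop("JZS marginal likelihood integration failed: ", marg$message)
  marg$value / stats::dt(t, df)
}

check_values_matrix <- function(values, group) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop("missing cells in the participant x condition table; no imputation")
  if (ncol(values) < 2L) stop("need at least 2 within-subject conditions")
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(table(group) < 2L)) stop("need at least 2 participants per group")
  if (nrow(values) != length(group))
    stop("one group label per participant row is required")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  list(values = values, group = group)
}

extract_split_plot <- function(fit, idata, pes_effects, test_label) {
  a <- car::Anova(fit, idata = idata, idesign = ~condition, type = 3)
  u <- suppressWarnings(summary(a, multivariate = FALSE))$univariate.tests
  rows <- lapply(pes_effects, function(eff) {
    i <- match(eff$row, rownames(u))
    if (is.na(i)) stop("effect not found in ANOVA table: ", eff$row)
    ss <- u[i, "Sum Sq"]
    sse <- u[i, "Error SS"]
    Fv <- u[i, "F value"]
    p <- u[i, "Pr(>F)"]
    pes <- ss / (ss + sse)
    if ((!is.finite(Fv) || (ss < 1e-12 && sse < 1e-12)) && ss < 1e-12) {
      # degenerate zero-variance data: no effect, by convention F = 0
      Fv <- 0; p <- 1; pes <- 0
    }
    stat_result(test_label, eff$label, Fv,
                u[i, "num Df"], u[i, "den Df"], p,
                effect_size = pes, notes = "partial_eta_sq")
  })
  do.call(rbind, rows)
}

#' Mixed repeated-measures ANOVA with partial eta squared
#'
#' Split-plot (univariate) ANOVA with one within-subject factor
#' (condition) and one between-subject factor (group), Type III sums of
#' squares with sum-to-zero contrasts, and uncorrected degrees of freedom
#' by default (Greenhouse-Geisser available as an option). Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`. At the study's design
#' size (18 + 18 participants, 3 conditions) the dfs are (2, 68) for the
#' within effects and (1, 34) for the group effect.
#'
#' @param values numeric matrix/data.frame, participants x conditions
#'   (complete; no imputation).
#' @param group per-participant group labels (two levels).
#' @param sphericity `"none"` (default) or `"GG"` for Greenhouse-Geisser
#'   corrected p values of the within effects.
#' @return A `stat_result` data.frame with rows `group`, `condition`,
#'   `condition:group`.
#' @export
rm_anova_mixed <- function(values, group, sphericity = c("none", "GG")) {
  sphericity <- match.arg(sphericity)
  v <- check_values_matrix(values, group)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  dat <- data.frame(group = v$group)
  fit <- stats::lm(v$values ~ group, data = dat)
  idata <- data.frame(condition = factor(colnames(v$values),
                                         levels = colnames(v$values)))
  out <- extract_split_plot(
    fit, idata,
    list(list(row = "group", label = "group"),
         list(row = "condition", label = "condition"),
         list(row = "group:condition", label = "condition:group")),
    "rm_anova")
  if (sphericity == "GG") {
    a <- car::Anova(fit, idata = idata, idesign = ~condition, type = 3)
    s <- suppressWarnings(summary(a, multivariate = FALSE))
    gg <- s$pval.adjustments
    for (rw in rownames(gg)) {
      lbl <- if (rw == "group:condition") "condition:group" else rw
      i <- match(lbl, out$effect)
      out$p[i] <- gg[rw, "Pr(>F[GG])"]
      out$df1[i] <- out$df1[i] * gg[rw, "GG eps"]
      out$df2[i] <- out$df2[i] * gg[rw, "GG eps"]
      out$notes[i] <- paste0(out$notes[i], "; GG-corrected")
    }
  }
  out
}

#' Mixed repeated-measures ANCOVA with a participant-level covariate
#'
#' The [rm_anova_mixed()] design with a centered continuous covariate
#' (e.g. VWM capacity) added to the between-subject model; the within
#' error then loses one participant-level df per within contrast, giving
#' interaction dfs of (2, 66) at 36 participants and 3 conditions.
#'
#' @param values participants x conditions matrix.
#' @param group per-participant group labels.
#' @param covariate per-participant numeric covariate.
#' @return A `stat_result` data.frame with rows `group`, `covariate`,
#'   `condition`, `condition:group`, `condition:covariate`.
#' @export
ancova_mixed <- function(values, group, covariate) {
  v <- check_values_matrix(values, group)
  covariate <- as.numeric(covariate)
  stopifnot(length(covariate) == nrow(v$values), all(is.finite(covariate)))
  if (stats::sd(covariate) == 0)
    stop("constant covariate; ANCOVA is undefined")
  cov_c <- covariate - mean(covariate)
  X <- stats::model.matrix(~ g + z, data.frame(g = v$group, z = cov_c))
  if (qr(X)$rank < ncol(X))
    stop("covariate is confounded with group (singular design)")
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  dat <- data.frame(group = v$group, covariate = cov_c)
  fit <- stats::lm(v$values ~ group + covariate, data = dat)
  idata <- data.frame(condition = factor(colnames(v$values),
                                         levels = colnames(v$values)))
  extract_split_plot(
    fit, idata,
    list(list(row = "group", label = "group"),
         list(row = "covariate", label = "covariate"),
         list(row = "condition", label = "condition"),
         list(row = "group:condition", label = "condition:group"),
         list(row = "covariate:condition", label = "condition:covariate")),
    "ancova")
}

#' Format a stat_result row in report style
#'
#' @param res a one-row `stat_result` data.frame.
#' @return A string like `"t(34) = 0.836, p = 0.409, d = 0.279, BF10 = 0.423"`.
#' @export
format_stat <- function(res) {
  stopifnot(nrow(res) == 1L)
  fmt_p <- function(p) if (p < 0.001) "p < 0.001" else
    sprintf("p = %.3f", p)
  if (res$test %in% c("rm_anova", "ancova")) {
    sprintf("F(%g, %g) = %.3f, %s, partial eta^2 = %.3f",
            res$df1, res$df2, res$statistic, fmt_p(res$p), res$effect_size)
  } else if (res$test == "pearson_r") {
    sprintf("r = %.3f, %s", res$statistic, fmt_p(res$p))
  } else {
    s <- sprintf("t(%g) = %.3f, %s", res$df1, res$statistic, fmt_p(res$p))
    if (!is.na(res$effect_size))
      s <- paste0(s, sprintf(", d = %.3f", res$effect_size))
    if (!is.na(res$bf10))
      s <- paste0(s, if (res$bf10 > 1000) ", BF10 > 1000" else
        sprintf(", BF10 = %.3f", res$bf10))
    s
  }
}
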