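# Statistical battery for risk-stratified PWV cohorts: group assignment by
# 10-year risk score, Pearson correlation, Bland-Altman agreement,
# Kruskal-Wallis with Dunn/Bonferroni post hoc, and Welch's t.

#' Assign cardiovascular risk groups from the 10-year risk score
#'
#' Three strata: low (< 10), intermediate (10 to 20, both boundaries
#' included), high (> 20); plus the merged two-group classification
#' low vs higher (intermediate + high).
#'
#' @param frs numeric risk scores in percent (finite, >= 0).
#' @return data.frame with `frs`, `group3` and `group2` factors.
#' @export
assign_groups <- function(frs) {
  if (any(!is.finite(frs)) || any(frs < 0))
    stop("risk scores must be finite and non-negative")
  g3 <- cut(frs, c(-Inf, 10, 20, Inf), right = FALSE,
            labels = c("low", "intermediate", "high"))
  # right-closed upper boundary: exactly 20 is intermediate
  g3[frs == 20] <- "intermediate"
  g2 <- factor(ifelse(g3 == "low", "low", "higher"),
               levels = c("low", "higher"))
  data.frame(frs = frs, group3 = g3, group2 = g2)
}

#' Bland-Altman agreement analysis
#'
#' Differences `x - y` summarized by their mean and the mean +/- 1.96
#' sample-SD limits of agreement.
#'
#' @param x,y paired measurements (equal length >= 2).
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, and the
#'   per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d); s <- sd(d)
  list(mean_diff = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       sd_diff = s, means = (x + y) / 2, diffs = d)
}

#' Kruskal-Wallis test with Dunn-Bonferroni post hoc
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value, followed by
#' pairwise rank-based comparisons: Dunn's z statistics on the pooled mean
#' ranks (default) or pairwise Wilcoxon rank-sum tests, with p-values
#' multiplied by the number of comparisons and capped at 1 (Bonferroni).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param posthoc `"dunn"` or `"wilcoxon"`.
#' @return List with `H`, `df`, `p_value` and a `posthoc` data.frame
#'   (pair, statistic, p_unadjusted, p_adjusted).
#' @export
kruskal_wallis_bonferroni <- function(groups, posthoc = c("dunn", "wilcoxon")) {
  posthoc <- match.arg(posthoc)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1) {
    kw_h <- 0; kw_p <- 1
  } else {
    kw <- kruskal.test(x, g)
    kw_h <- unname(kw$statistic); kw_p <- kw$p.value
  }
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  ph <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (posthoc == "dunn") {
      s2 <- (N * (N + 1) / 12 - tie_term) * (1 / n[a] + 1 / n[b])
      z <- if (s2 > 0) (mean_rank[a] - mean_rank[b]) / sqrt(s2) else 0
      p <- 2 * pnorm(-abs(z))
      data.frame(pair = paste(a, b, sep = "-"), statistic = unname(z),
                 p_unadjusted = p, stringsAsFactors = FALSE)
    } else {
      w <- suppressWarnings(stats::wilcox.test(groups[[a]], groups[[b]]))
      data.frame(pair = paste(a, b, sep = "-"),
                 statistic = unname(w$statistic),
                 p_unadjusted = w$p.value, stringsAsFactors = FALSE)
    }
  })
  ph <- do.call(rbind, ph)
  ph$p_adjusted <- pmin(ph$p_unadjusted * m, 1)
  list(H = kw_h, df = length(groups) - 1, p_value = kw_p, posthoc = ph,
       method = posthoc)
}

#' Welch's unequal-variance t-test
#'
#' @param a,b numeric vectors (each >= 2 values; at least one with nonzero
#'   variance).
#' @return List with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) stop("both samples have zero variance")
    stop("both samples have zero variance; t is undefined")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors (>= 3 pairs, nonzero variance).
#' @return List with `r` and the t-based two-sided `p`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Ordinary least-squares line
#'
#' @param x,y numeric vectors (>= 3 pairs).
#' @return List with `slope`, `intercept` and the correlation `r`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(sign(coef(fit)[2]) * sqrt(r2)))
}

#' Normality and variance-homogeneity diagnostics per group
#'
#' Shapiro-Wilk p per group and the max/min variance ratio. Reported for
#' the analyst's judgement; no test is switched automatically.
#'
#' @param groups named list of numeric vectors.
#' @return List with per-group `shapiro_p` and the `variance_ratio`.
#' @export
group_diagnostics <- function(groups) {
  sp <- vapply(groups, function(v)
    if (length(v) >= 3 && var(v) > 0) shapiro.test(v)$p.value else NA_real_,
    numeric(1))
  vr <- {
    vv <- vapply(groups, var, numeric(1))
    if (min(vv) > 0) max(vv) / min(vv) else Inf
  }
  list(shapiro_p = sp, variance_ratio = vr)
}

#' Full statistical report for a PWV cohort
#'
#' Runs the cohort battery: Pearson correlation and Bland-Altman agreement
#' between the imaging and theoretical PWV, Kruskal-Wallis with
#' Dunn-Bonferroni across the three risk groups (for each measure), Welch's
#' t between the merged two groups, the linear fit of the imaging PWV on
#' the risk score, and group summaries/diagnostics.
#'
#' @param cohort a `cohort_table` (see [generate_cohort()] or
#'   [read_cohort()]).
#' @param posthoc post-hoc flavour, see [kruskal_wallis_bonferroni()].
#' @return A nested list, serializable to JSON.
#' @export
stats_report <- function(cohort, posthoc = "dunn") {
  ga <- assign_groups(cohort$frs)
  by3 <- function(v) split(v, ga$group3)
  by2 <- function(v) split(v, ga$group2)
  summarize <- function(v) {
    s3 <- lapply(by3(v), function(u) list(n = length(u), mean = mean(u),
                                          sd = sd(u)))
    s3
  }
  ba <- bland_altman(cohort$ufcpwv, cohort$bhpwv)
  list(
    n = nrow(cohort),
    pearson_ufc_bh = pearson(cohort$ufcpwv, cohort$bhpwv),
    bland_altman = ba[c("mean_diff", "loa_low", "loa_high", "sd_diff")],
    kw_ufcpwv = kruskal_wallis_bonferroni(by3(cohort$ufcpwv), posthoc),
    kw_bhpwv = kruskal_wallis_bonferroni(by3(cohort$bhpwv), posthoc),
    welch_ufcpwv = welch_t(by2(cohort$ufcpwv)$low, by2(cohort$ufcpwv)$higher),
    welch_bhpwv = welch_t(by2(cohort$bhpwv)$low, by2(cohort$bhpwv)$higher),
    fit_ufc_frs = linear_fit(cohort$frs, cohort$ufcpwv),
    group_summary_ufcpwv = summarize(cohort$ufcpwv),
    group_summary_bhpwv = summarize(cohort$bhpwv),
    diagnostics_ufcpwv = group_diagnostics(by3(cohort$ufcpwv)))
}
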