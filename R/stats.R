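# Coerce the `groups` argument: a named list of numeric vectors, or a
# data frame with `group` and `value` columns.
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    cv_assert(all(c("group", "value") %in% names(groups)),
              "charvoid_validation_error",
              "a data-frame input needs group and value columns")
    groups <- split(groups$value, groups$group)
  }
  cv_assert(is.list(groups) && length(groups) >= 2,
            "charvoid_validation_error", "need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

check_group_sizes <- function(groups, min_n = 2L) {
  sizes <- lengths(groups)
  cv_assert(all(sizes >= min_n), "charvoid_validation_error",
            "every group needs at least %d values", min_n)
  sizes
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the F statistic is the ratio of
#' the between-group to the within-group mean square, with a p-value from
#' the F distribution. Fitted with [stats::aov()].
#'
#' @param groups Named list of numeric vectors (one per group), or a data
#'   frame with `group`/`value` columns. Each group needs `>= 2` values
#'   and the pooled within-group variance must be nonzero.
#' @return List with `F`, `df` (between, within), `p`, `group_means`,
#'   `ms_within` and `df_within` (the pooled error term reused by
#'   [fisher_lsd()]).
#' @export
oneway_anova <- function(groups) {
  groups <- as_group_list(groups)
  check_group_sizes(groups)
  cv_assert(any(vapply(groups, stats::var, 0) > 0), "charvoid_degenerate",
            "zero within-group variance: ANOVA is undefined")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  list(
    F = tab[1, "F value"],
    df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
    p = tab[1, "Pr(>F)"],
    group_means = vapply(groups, mean, 0),
    ms_within = tab[2, "Mean Sq"],
    df_within = tab[2, "Df"]
  )
}

#' Choose the post-hoc family from a variance-homogeneity gate
#'
#' Levene's test (mean-centered) at the given alpha: when the hypothesis
#' of equal variances is not rejected the equal-variance Fisher LSD family
#' is used, otherwise Dunnett's T3 (which assumes nothing about the
#' variances). This mirrors the conventional SPSS-style workflow for such
#' data.
#'
#' @inheritParams oneway_anova
#' @param alpha Gate level.
#' @return List with `homogeneity_p` (Levene p-value) and
#'   `posthoc_method` (`"LSD"` or `"DunnettT3"`).
#' @export
variance_gate <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  check_group_sizes(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  if (all(vapply(groups, stats::var, 0) == 0)) {
    # identical spreads: trivially homogeneous
    p <- 1
  } else {
    p <- car::leveneTest(value ~ group, data = df, center = mean)[1, "Pr(>F)"]
  }
  list(homogeneity_p = p,
       posthoc_method = if (p >= alpha) "LSD" else "DunnettT3")
}

pairwise_skeleton <- function(groups) {
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  tibble::tibble(
    group_i = names(groups)[pairs[1, ]],
    group_j = names(groups)[pairs[2, ]],
    i = pairs[1, ], j = pairs[2, ]
  )
}

#' Fisher's least significant difference post-hoc tests
#'
#' Pairwise two-sided t tests sharing the pooled ANOVA error term
#' (`ms_within` on `df_within` degrees of freedom); appropriate when the
#' group variances are equal.
#'
#' @inheritParams oneway_anova
#' @param conf_level Confidence level of the reported intervals.
#' @return Tibble, one row per unordered pair: `group_i`, `group_j`,
#'   `mean_diff` (i minus j), `se`, `t`, `df`, `p`, `ci_lo`, `ci_hi`.
#' @export
fisher_lsd <- function(groups, conf_level = 0.95) {
  groups <- as_group_list(groups)
  an <- oneway_anova(groups)
  out <- pairwise_skeleton(groups)
  n <- unname(lengths(groups))
  m <- unname(vapply(groups, mean, 0))
  out$mean_diff <- m[out$i] - m[out$j]
  out$se <- sqrt(an$ms_within * (1 / n[out$i] + 1 / n[out$j]))
  out$t <- out$mean_diff / out$se
  out$df <- an$df_within
  out$p <- 2 * stats::pt(-abs(out$t), out$df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, out$df)
  out$ci_lo <- out$mean_diff - crit * out$se
  out$ci_hi <- out$mean_diff + crit * out$se
  out$i <- out$j <- NULL
  out
}

# Tail probability of the studentized maximum modulus: the probability
# that the largest of k independent |t_nu| variates exceeds q. For
# independent t variates P(max |T| <= q) = (2 F_nu(q) - 1)^k, exact at any
# df; treating the pairwise statistics as independent is the conservative
# classical construction.
smm_p <- function(q, df, k) {
  1 - pmax(0, 2 * stats::pt(abs(q), df) - 1)^k
}

# Monte-Carlo estimate of the same tail probability (cross-check).
smm_p_mc <- function(q, df, k, reps = 1e5, rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    m <- matrix(abs(stats::rt(reps * k, df)), reps, k)
    mean(apply(m, 1, max) >= abs(q))
  })
}

#' Dunnett's T3 post-hoc tests for unequal variances
#'
#' Welch t statistics per pair with Welch-Satterthwaite degrees of
#' freedom; the family-wise adjustment refers each statistic to the
#' studentized maximum modulus over the number of pairwise comparisons,
#' evaluated exactly from the t distribution.
#'
#' @inheritParams oneway_anova
#' @param conf_level Confidence level of the simultaneous intervals.
#' @return Tibble, one row per unordered pair: `group_i`, `group_j`,
#'   `mean_diff`, `se`, `t`, `df` (Welch-Satterthwaite), `p` (family-wise
#'   adjusted), `p_unadjusted`, `ci_lo`, `ci_hi`.
#' @export
dunnett_t3 <- function(groups, conf_level = 0.95) {
  groups <- as_group_list(groups)
  check_group_sizes(groups)
  out <- pairwise_skeleton(groups)
  n <- unname(lengths(groups))
  m <- unname(vapply(groups, mean, 0))
  s2 <- unname(vapply(groups, stats::var, 0))
  k_star <- nrow(out)
  vi <- s2[out$i] / n[out$i]
  vj <- s2[out$j] / n[out$j]
  out$mean_diff <- m[out$i] - m[out$j]
  out$se <- sqrt(vi + vj)
  out$df <- (vi + vj)^2 /
    (vi^2 / (n[out$i] - 1) + vj^2 / (n[out$j] - 1))
  out$t <- out$mean_diff / out$se
  out$p_unadjusted <- 2 * stats::pt(-abs(out$t), out$df)
  out$p <- smm_p(out$t, out$df, k_star)
  # simultaneous intervals from the SMM critical value at each pair's df
  alpha <- 1 - conf_level
  crit <- stats::qt((1 + (1 - alpha)^(1 / k_star)) / 2, out$df)
  out$ci_lo <- out$mean_diff - crit * out$se
  out$ci_hi <- out$mean_diff + crit * out$se
  out$i <- out$j <- NULL
  out[, c("group_i", "group_j", "mean_diff", "se", "t", "df",
          "p", "p_unadjusted", "ci_lo", "ci_hi")]
}

#' Two-tailed t test between two samples
#'
#' Student's pooled-variance test by default, Welch's when `welch = TRUE`.
#'
#' @param a,b Numeric samples, each with `>= 2` values.
#' @param welch Use the Welch (unequal variance) form.
#' @return List with `t`, `df`, `p`, `mean_diff`, `ci`.
#' @export
t_test_two_tailed <- function(a, b, welch = FALSE) {
  cv_assert(length(a) >= 2 && length(b) >= 2, "charvoid_validation_error",
            "each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    cv_stop("charvoid_degenerate",
            "both samples are constant and equal: t is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(a) - mean(b),
       ci = unname(ht$conf.int))
}

#' Full group comparison: ANOVA, variance gate and both post-hoc families
#'
#' Runs the complete comparison used for per-seed category counts: one-way
#' ANOVA, the Levene gate choosing between Fisher's LSD and Dunnett's T3,
#' and both post-hoc tables (so either family can be inspected regardless
#' of the gate's choice).
#'
#' @inheritParams oneway_anova
#' @param alpha Significance level recorded in the result.
#' @return List of class `group_comparison`: `anova`, `homogeneity_p`,
#'   `posthoc_method`, `lsd`, `dunnett_t3`, `posthoc` (the gated table),
#'   `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  an <- oneway_anova(groups)
  gate <- variance_gate(groups, alpha)
  lsd <- fisher_lsd(groups)
  t3 <- dunnett_t3(groups)
  structure(list(
    anova = an,
    homogeneity_p = gate$homogeneity_p,
    posthoc_method = gate$posthoc_method,
    lsd = lsd, dunnett_t3 = t3,
    posthoc = if (gate$posthoc_method == "LSD") lsd else t3,
    alpha = alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  cat(sprintf("Levene (mean-centered) p = %.4g -> %s\n",
              x$homogeneity_p, x$posthoc_method))
  print(x$posthoc, ...)
  invisible(x)
}
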