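#' Statistics configuration
#'
#' @param alpha significance level for the normality gate and reporting;
#'   default 0.05. All tests are two-sided.
#' @return a `stats_config` list.
#' @export
stats_config <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = as.numeric(alpha), normality_test = "shapiro-wilk",
                 two_sided = TRUE),
            class = "stats_config")
}

#' Normality-gated two-sample test
#'
#' Both samples are tested for normality with the Shapiro-Wilk test at
#' `alpha`; if both pass, a two-tailed Welch t test is run, otherwise a
#' two-tailed Mann-Whitney U test. The gate decision is reported alongside
#' the p-value.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 3.
#' @param cfg a [stats_config()].
#' @return list: `test` ("welch_t" or "mann_whitney_u"), `p_value`,
#'   `statistic`, `shapiro_p` (length 2), `gate` ("both_normal" or
#'   "not_normal"), `alpha`, `n` (length 2).
#' @examples
#' choose_test(rnorm(20), rnorm(20, 1))$test
#' @export
choose_test <- function(sample_a, sample_b, cfg = stats_config()) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop("each sample needs n >= 3 for the normality gate")
  }
  sw <- c(a = shapiro_p_safe(sample_a), b = shapiro_p_safe(sample_b))
  both_normal <- all(sw > cfg$alpha)
  if (both_normal) {
    res <- welch_t(sample_a, sample_b)
    list(test = "welch_t", p_value = res$p, statistic = res$t,
         df = res$df, shapiro_p = sw, gate = "both_normal",
         alpha = cfg$alpha, n = c(length(sample_a), length(sample_b)))
  } else {
    res <- mann_whitney_u(sample_a, sample_b)
    list(test = "mann_whitney_u", p_value = res$p, statistic = res$U,
         shapiro_p = sw, gate = "not_normal", alpha = cfg$alpha,
         n = c(length(sample_a), length(sample_b)))
  }
}

# shapiro.test errors on zero-range samples; treat those as non-normal
shapiro_p_safe <- function(x) {
  if (length(unique(x)) == 1) return(0)
  shapiro.test(x)$p.value
}

#' Welch two-sample t test
#'
#' Two-tailed t test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), delegated to [stats::t.test()].
#' Two samples with zero variance and equal means give t = 0, p = 1; zero
#' variance with unequal means is an error (the statistic is undefined).
#'
#' @param sample_a,sample_b numeric vectors of length >= 2.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    stop("both samples have zero variance with unequal means: t undefined")
  }
  res <- t.test(sample_a, sample_b, var.equal = FALSE,
                alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Mann-Whitney U test
#'
#' Two-tailed rank-sum test. For `n_a + n_b <= 12` the p-value is exact:
#' the permutation distribution of U is enumerated over all
#' choose(n_a + n_b, n_a) group assignments of the pooled mid-ranks (so
#' ties are handled exactly), and the two-sided p is the probability of a
#' U at least as far from its null mean `n_a n_b / 2` as observed. For
#' larger samples a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param sample_a,sample_b numeric vectors, length >= 1.
#' @param exact_max maximum pooled size for exact enumeration; default 12.
#' @return list: `U` (for sample_a), `p`, `method` ("exact" or
#'   "normal_approx").
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_max = 12L) {
  na <- length(sample_a); nb <- length(sample_b)
  stopifnot(na >= 1, nb >= 1)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                  # mid-ranks under ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na + nb <= exact_max) {
    idx <- combn(na + nb, na)
    ranksums <- colSums(matrix(r[idx], nrow = na))
    u_all <- ranksums - na * (na + 1) / 2
    # exact two-sided: mass at least as extreme about the null mean
    eps <- 1e-9
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    list(U = u_obs, p = p, method = "exact")
  } else {
    n <- na + nb
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) return(list(U = u_obs, p = 1, method = "normal_approx"))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    list(U = u_obs, p = min(1, 2 * pnorm(-abs(z))), method = "normal_approx")
  }
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule (sum of hypergeometric
#' probabilities of tables, at fixed margins, no more probable than the
#' observed one), delegated to [stats::fisher.test()]. Reports the sample
#' odds ratio and the conditional-MLE odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `p`, `odds_ratio_sample` (ad/bc), `odds_ratio_cmle`.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate 2x2 table: a margin is zero")
  }
  res <- fisher.test(table, alternative = "two.sided")
  or_sample <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p = res$p.value, odds_ratio_sample = or_sample,
       odds_ratio_cmle = unname(res$estimate))
}

#' Hierarchical experiment-level summary
#'
#' Per-experiment means (the "triangles" of a superplot) plus the overall
#' mean and s.e.m. on a declared basis: across experiment means
#' (`basis = "experiments"`) or across all units (`basis = "units"`). With
#' a single experiment (or unit) the s.e.m. is reported as 0 and flagged.
#'
#' @param values numeric vector of per-unit measurements.
#' @param experiment parallel vector of experiment labels.
#' @param basis `"experiments"` or `"units"`.
#' @return a `hierarchical_summary`: `experiment_means` (named),
#'   `overall_mean`, `sem`, `basis`, `n_experiments`, `n_units`,
#'   `single_basis_flag`.
#' @examples
#' summarize_hierarchical(c(1, 2, 3, 4, 5, 6),
#'                        rep(c("e1", "e2"), each = 3))
#' @export
summarize_hierarchical <- function(values, experiment,
                                   basis = c("experiments", "units")) {
  basis <- match.arg(basis)
  stopifnot(length(values) == length(experiment), length(values) >= 1)
  em <- vapply(split(values, experiment), mean, 0)
  if (basis == "experiments") {
    overall <- mean(em)
    n_basis <- length(em)
    sem <- if (n_basis < 2) 0 else sd(em) / sqrt(n_basis)
  } else {
    overall <- mean(values)
    n_basis <- length(values)
    sem <- if (n_basis < 2) 0 else sd(values) / sqrt(n_basis)
  }
  structure(list(experiment_means = em, overall_mean = overall, sem = sem,
                 basis = basis, n_experiments = length(em),
                 n_units = length(values),
                 single_basis_flag = n_basis < 2),
            class = "hierarchical_summary")
}

#' @export
print.hierarchical_summary <- function(x, ...) {
  cat(sprintf("<hierarchical_summary> overall %.4g +/- %.4g s.e.m. (basis: %s; %d experiments, %d units)\n",
              x$overall_mean, x$sem, x$basis, x$n_experiments, x$n_units))
  cat("  experiment means:",
      paste(sprintf("%s=%.4g", names(x$experiment_means),
                    x$experiment_means), collapse = ", "), "\n")
  invisible(x)
}
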