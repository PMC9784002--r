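#' Validate a grading by ANOVA, Levene's test and SNK-q contrasts
#'
#' Checks that the three-level grading separates the fitted RSR values:
#' one-way ANOVA of fitted RSR across grade groups, Levene's test (Brown-
#' Forsythe variant, centring at the group median) for homogeneity of
#' variance, and Student-Newman-Keuls stepwise studentized-range pairwise
#' comparisons at `alpha`. Because fitted RSR is an affine transform of the
#' probit, the F statistic is identical whether computed on fitted values or
#' probits.
#'
#' Grade groups with fewer than 2 members are kept in the ANOVA but excluded
#' from the SNK step (with a warning), since a singleton group has no
#' within-group variance contribution of its own.
#'
#' @param fit an [rsr_fit()], or a numeric vector of values with `groups`
#'   given.
#' @param groups grouping factor, required when `fit` is a plain vector.
#' @param alpha significance level for the SNK-q verdicts (default 0.05).
#' @return an object of class `rsr_grade_test`: list with `anova_F`,
#'   `anova_p`, `levene_stat`, `levene_p`, `snk` (data.frame: `group1`,
#'   `group2`, `span`, `q`, `q_crit`, `significant`), and `group_sizes`.
#' @examples
#' fit <- rsr_fit(maternal_rsr(2009, "needs"))
#' validate_grades(fit)   # F about 36.4, all pairs significant
#' @export
validate_grades <- function(fit, groups = NULL, alpha = 0.05) {
  if (inherits(fit, "rsr_fit")) {
    values <- unname(fit$fitted_rsr)
    groups <- factor(fit$grade)
  } else {
    values <- as.numeric(fit)
    if (is.null(groups)) stop("groups required when fit is not an rsr_fit")
    groups <- factor(groups)
  }
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 non-empty grade groups, got ", nlevels(groups))

  av <- aov(values ~ groups)
  at <- anova(av)
  anova_F <- at[["F value"]][1]
  anova_p <- at[["Pr(>F)"]][1]
  mse <- at[["Mean Sq"]][2]
  df_err <- at[["Df"]][2]

  lev <- car::leveneTest(values ~ groups, center = stats::median)
  snk <- snk_test(values, groups, alpha = alpha, mse = mse, df_error = df_err)

  structure(list(
    anova_F = anova_F, anova_p = anova_p,
    levene_stat = lev[["F value"]][1], levene_p = lev[["Pr(>F)"]][1],
    snk = snk,
    group_sizes = table(groups),
    alpha = alpha
  ), class = "rsr_grade_test")
}

#' Student-Newman-Keuls stepwise studentized-range test
#'
#' Orders the group means and compares each pair with the studentized range
#' statistic \eqn{q = (\bar y_i - \bar y_j) / \sqrt{(MS_e/2)(1/n_i + 1/n_j)}}
#' against the critical value `qtukey(1 - alpha, p, df)`, where `p` is the
#' number of means spanned by the pair (the step). Stepwise protection
#' applies: a pair is declared non-significant, without testing, whenever a
#' wider pair containing it already failed.
#'
#' @param values numeric response vector.
#' @param groups grouping factor.
#' @param alpha significance level (default 0.05).
#' @param mse,df_error error mean square and df; taken from the one-way ANOVA
#'   of `values ~ groups` when omitted.
#' @return data.frame with one row per pair of groups (with >= 2 members):
#'   `group1`, `group2`, `span`, `q`, `q_crit`, `significant`.
#' @export
snk_test <- function(values, groups, alpha = 0.05,
                     mse = NULL, df_error = NULL) {
  groups <- droplevels(factor(groups))
  if (is.null(mse) || is.null(df_error)) {
    at <- anova(aov(values ~ groups))
    mse <- at[["Mean Sq"]][2]
    df_err <- at[["Df"]][2]
  } else df_err <- df_error
  ns <- tapply(values, groups, length)
  small <- names(ns)[ns < 2]
  if (length(small)) {
    warning("grade group(s) with < 2 members excluded from SNK: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
    ns <- tapply(values, groups, length)
  }
  k <- nlevels(groups)
  if (k < 2L) stop("SNK needs at least 2 groups with >= 2 members")
  means <- tapply(values, groups, mean)
  ord <- order(means)          # ascending
  res <- NULL
  nonsig <- matrix(FALSE, k, k) # in ordered index space
  # test pairs from widest span downward (stepwise protection)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      gi <- ord[i]; gj <- ord[j]
      q <- (means[gj] - means[gi]) /
        sqrt(mse / 2 * (1 / ns[gi] + 1 / ns[gj]))
      qc <- qtukey(1 - alpha, span, df_err)
      blocked <- nonsig[i, j]
      sig <- !blocked && q > qc
      if (!sig) {
        # all pairs nested inside [i, j] are declared non-significant
        for (ii in i:j) for (jj in ii:j) nonsig[ii, jj] <- TRUE
      }
      res <- rbind(res, data.frame(
        group1 = levels(groups)[gi], group2 = levels(groups)[gj],
        span = span, q = unname(q), q_crit = qc,
        significant = unname(sig), stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- NULL
  res
}

#' @export
print.rsr_grade_test <- function(x, ...) {
  cat(sprintf("Grading validation (alpha = %g)\n", x$alpha))
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.3g\n", x$anova_F, x$anova_p))
  cat(sprintf("  Levene (median-centred): F = %.3f, p = %.3g\n",
              x$levene_stat, x$levene_p))
  cat("  group sizes: ",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  SNK-q pairwise:\n")
  for (i in seq_len(nrow(x$snk)))
    cat(sprintf("    %s vs %s: q = %.2f (crit %.2f) %s\n",
                x$snk$group1[i], x$snk$group2[i], x$snk$q[i], x$snk$q_crit[i],
                if (x$snk$significant[i]) "significant" else "n.s."))
  invisible(x)
}
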