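#' Fit the RSR~probit grading line and assign three-level grades
#'
#' The central model of the RSR method. The empirical RSR distribution is
#' expressed on the probit scale (see [rsr_probit()]) and an ordinary
#' least-squares line
#' \deqn{\widehat{RSR} = a + b \times probit}
#' is fitted with RSR as the response. Substituting the probit cut-offs
#' (default 4 and 6, i.e. one standard deviation below and above the probit
#' mean of 5) into the full-precision fitted line gives the critical RSR
#' values separating the grades; each unit is graded `Low` if its probit is
#' `<= cuts[1]`, `High` if `>= cuts[2]`, otherwise `Medium`.
#'
#' Grading uses the unrounded coefficients throughout: critical values
#' recomputed from rounded published coefficients can differ in the third
#' decimal.
#'
#' @param rsr numeric vector of RSR scores (named by unit), or an
#'   [rsr_probit()] object.
#' @param cuts strictly increasing numeric vector of probit cut-offs,
#'   default `c(4, 6)`. `length(cuts) + 1` grades result; the default gives
#'   the common three-grading scheme labelled Low/Medium/High.
#' @param ties tie handling passed to [rsr_probit()] when `rsr` is a plain
#'   vector.
#' @return an object of class `rsr_fit`: a list with elements
#'   \describe{
#'     \item{dist}{the [rsr_probit()] data.frame}
#'     \item{lm}{the underlying [stats::lm()] fit}
#'     \item{a, b}{intercept and slope}
#'     \item{r}{Pearson correlation of RSR and probit}
#'     \item{r_adj}{adjusted R-squared of the fit (the goodness-of-fit figure
#'       conventionally reported alongside RSR regression equations)}
#'     \item{p_value}{regression F-test p-value}
#'     \item{cuts, critical_rsr}{probit cut-offs and fitted RSR at each}
#'     \item{fitted_rsr}{per-unit fitted RSR (`a + b * probit`)}
#'     \item{grade}{ordered factor Low < Medium < High}
#'   }
#' @seealso [validate_grades()], [classify_regions()], [rsr_evaluate()]
#' @examples
#' rsr <- maternal_fixture(2009, "rsr")
#' x <- setNames(rsr$rsr[rsr$dimension == "needs"],
#'               rsr$region[rsr$dimension == "needs"])
#' fit <- rsr_fit(x)
#' coef(fit)                # a, b
#' fit$critical_rsr         # approx 0.158, 0.422
#' table(fit$grade)         # 4 Low, 22 Medium, 5 High
#' predict(fit, probit = 5) # fitted RSR at the probit mean
#' @export
rsr_fit <- function(rsr, cuts = c(4, 6), ties = c("average", "first")) {
  if (inherits(rsr, "rsr_probit")) {
    dist <- rsr
  } else {
    dist <- rsr_probit(rsr, ties = match.arg(ties))
  }
  if (length(cuts) < 1L || is.unsorted(cuts, strictly = TRUE))
    stop("probit cuts must be strictly increasing")
  if (var(dist$probit) == 0) stop("probit values are constant; cannot fit")

  fit <- lm(rsr ~ probit, data = dist)
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  sm <- summary(fit)
  grade <- grade_levels(length(cuts))
  g <- cut(dist$probit,
           breaks = c(-Inf, cuts, Inf),
           labels = grade, right = FALSE, ordered_result = TRUE)
  # boundary convention: Low iff probit <= cuts[1], High iff probit >= last cut
  g[dist$probit <= cuts[1]] <- grade[1]
  g[dist$probit >= cuts[length(cuts)]] <- grade[length(grade)]
  structure(list(
    dist = dist,
    lm = fit,
    a = a, b = b,
    r = cor(dist$probit, dist$rsr),
    r_adj = sm$adj.r.squared,
    p_value = unname(pf_from(sm)),
    cuts = cuts,
    critical_rsr = a + b * cuts,
    fitted_rsr = setNames(a + b * dist$probit, dist$unit),
    grade = setNames(g, dist$unit),
    n = attr(dist, "n")
  ), class = "rsr_fit")
}

grade_levels <- function(ncuts) {
  if (ncuts == 2L) c("Low", "Medium", "High")
  else paste0("G", seq_len(ncuts + 1L))
}

pf_from <- function(sm) {
  f <- sm$fstatistic
  if (is.null(f)) return(NA_real_)
  stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
}

#' @export
print.rsr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("RSR ~ probit grading fit (n = %d)\n", x$n))
  cat(sprintf("  RSR-hat = %.3f x probit %+.3f   (r = %.3f, adj R2 = %.3f)\n",
              x$b, x$a, x$r, x$r_adj))
  cat("  probit cuts: ", paste(x$cuts, collapse = ", "),
      "  critical RSR: ",
      paste(sprintf("%.3f", x$critical_rsr), collapse = ", "), "\n", sep = "")
  print(table(x$grade))
  invisible(x)
}

#' @export
coef.rsr_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
fitted.rsr_fit <- function(object, ...) object$fitted_rsr

#' @export
residuals.rsr_fit <- function(object, ...) {
  setNames(object$dist$rsr - object$fitted_rsr, object$dist$unit)
}

#' Fitted RSR at new probit values
#'
#' @param object an [rsr_fit()].
#' @param probit numeric vector of probit values; defaults to the fitted
#'   units' probits.
#' @param ... unused.
#' @return numeric vector `a + b * probit`.
#' @export
predict.rsr_fit <- function(object, probit = NULL, ...) {
  if (is.null(probit)) return(object$fitted_rsr)
  object$a + object$b * probit
}

#' @export
summary.rsr_fit <- function(object, ...) {
  structure(list(fit = object, validation = validate_grades(object)),
            class = "summary.rsr_fit")
}

#' @export
print.summary.rsr_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$validation)
  invisible(x)
}

#' @export
plot.rsr_fit <- function(x, main = "RSR ~ probit", ...) {
  graphics::plot(x$dist$probit, x$dist$rsr,
                 xlab = "probit", ylab = "RSR",
                 pch = 19, col = c(Low = "firebrick", Medium = "grey30",
                                   High = "forestgreen")[as.character(x$grade)],
                 main = main, ...)
  abline(a = x$a, b = x$b, lwd = 2, col = "steelblue")
  abline(v = x$cuts, lty = 2, col = "grey60")
  legend("topleft", bty = "n", pch = 19,
         col = c("firebrick", "grey30", "forestgreen"),
         legend = levels(x$grade))
  invisible(x)
}
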