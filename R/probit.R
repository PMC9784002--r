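#' Downward cumulative frequency and probit of an RSR vector
#'
#' Sorts the RSR values from small to large, computes each unit's tie-averaged
#' ascending rank, the downward cumulative frequency
#' \eqn{P = \bar R / n \times 100\%}, and the classical probit
#' \eqn{\Phi^{-1}(P/100) + 5}, so that \eqn{P = 50\%} maps to probit exactly
#' 5. The top unit's \eqn{P = 100\%} would have an infinite probit and is
#' replaced by the standard correction \eqn{100\,(1 - 1/(4n))} (99.19...\% for
#' `n = 31`).
#'
#' Exactly tied RSR values receive the same averaged rank, hence the same `P`
#' and probit, under the default `ties = "average"`. `ties = "first"` instead
#' breaks exact ties by order of appearance; it is useful when reproducing
#' published tables whose underlying unrounded values differed but print as
#' tied.
#'
#' @param rsr numeric vector of RSR scores, length `n >= 2`; names are kept as
#'   unit identifiers.
#' @param ties `"average"` (default) or `"first"`.
#' @return an object of class `rsr_probit`: a data.frame with columns `unit`,
#'   `rsr`, `avg_rank`, `p` (percent, in `(0, 100)`) and `probit`, in the
#'   input order, with attributes `n` and `ties`.
#' @examples
#' d <- rsr_probit(c(a = 0.1, b = 0.2, c = 0.3, d = 0.4))
#' d$p       # 25 50 75 93.75 (the 100% correction: 100 * (1 - 1/16))
#' d$probit  # qnorm(p/100) + 5
#' @export
rsr_probit <- function(rsr, ties = c("average", "first")) {
  ties <- match.arg(ties)
  n <- length(rsr)
  if (n < 2L) stop("need at least 2 RSR values, got ", n)
  if (!is.numeric(rsr) || anyNA(rsr) || any(!is.finite(rsr)))
    stop("RSR values must be finite and non-missing")
  units <- if (is.null(names(rsr))) paste0("unit", seq_len(n)) else names(rsr)
  avg_rank <- rank(rsr, ties.method = ties)
  p <- avg_rank / n * 100
  p[p >= 100] <- 100 * (1 - 1 / (4 * n))
  out <- data.frame(unit = units, rsr = unname(rsr),
                    avg_rank = unname(avg_rank), p = unname(p),
                    probit = qnorm(unname(p) / 100) + 5,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "ties") <- ties
  class(out) <- c("rsr_probit", "data.frame")
  out
}

#' @export
print.rsr_probit <- function(x, digits = 3, ...) {
  cat("RSR distribution (n = ", attr(x, "n"), ", ties = ",
      attr(x, "ties"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$rsr <- round(df$rsr, digits)
  df$p <- round(df$p, 1)
  df$probit <- round(df$probit, digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}
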