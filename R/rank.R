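#' Non-integer rank transformation of one indicator
#'
#' Linearly interpolates ranks between 1 and `n` from an indicator's value
#' relative to the column minimum and maximum, so that quantitative distance
#' between regions is retained (classical integer ranks discard it). For a
#' high-quality indicator (larger is better)
#' \deqn{R = 1 + (n-1)\,(X - X_{min})/(X_{max} - X_{min}),}
#' and for a low-quality indicator (larger is worse, e.g. a mortality rate)
#' \deqn{R = 1 + (n-1)\,(X_{max} - X)/(X_{max} - X_{min}),}
#' so the best region always receives rank `n` and the worst rank 1, and
#' `rsr_rank(x, "low_quality") == n + 1 - rsr_rank(x, "high_quality")`.
#'
#' A constant column carries no information; every unit then receives the
#' midpoint rank `(1 + n) / 2` (the unique orientation-symmetric choice) and a
#' warning is emitted.
#'
#' @param x numeric vector of raw indicator values, length `n >= 2`, finite.
#' @param orientation `"high_quality"` (default) or `"low_quality"`.
#' @return numeric vector of ranks in `[1, n]`.
#' @seealso [rsr_score()], [rsr_dimensions()]
#' @examples
#' rsr_rank(c(10, 20, 40))                  # 1.0 1.667 3.0
#' rsr_rank(c(10, 20, 40), "low_quality")   # 3.0 2.333 1.0
#' @export
rsr_rank <- function(x, orientation = c("high_quality", "low_quality")) {
  orientation <- match.arg(orientation)
  if (length(x) < 2L)
    stop("need at least 2 values to rank, got ", length(x))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("indicator values must be finite and non-missing")
  n <- length(x)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant indicator column: assigning midpoint rank (1 + n)/2 to all units")
    return(rep((1 + n) / 2, n))
  }
  r <- if (orientation == "high_quality") {
    1 + (n - 1) * (x - rng[1]) / (rng[2] - rng[1])
  } else {
    1 + (n - 1) * (rng[2] - x) / (rng[2] - rng[1])
  }
  pmin(pmax(r, 1), n)  # guard against last-ulp rounding past the bounds
}

#' Rank Sum Ratio of a rank matrix
#'
#' Averages a unit's ranks across the `m` indicators of one dimension and
#' scales by the number of units:
#' \deqn{RSR_i = \frac{1}{m\,n} \sum_{j=1}^{m} R_{ij},}
#' giving a dimensionless score in \eqn{[1/n, 1]}: a unit ranked 1 on every
#' indicator scores `1/n`, a unit ranked `n` everywhere scores 1. All
#' indicators carry equal weight.
#'
#' @param ranks numeric matrix (`n` units x `m` indicators) of ranks in
#'   `[1, n]`, e.g. columns of [rsr_rank()] output.
#' @return numeric vector of `n` RSR scores (named after rownames).
#' @examples
#' rsr_score(cbind(c(1, 3, 2), c(2, 1, 3)))  # 0.5 0.667 0.833
#' @export
rsr_score <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (ncol(ranks) < 1L) stop("rank matrix has no indicator columns")
  n <- nrow(ranks)
  if (n < 2L) stop("rank matrix needs at least 2 units")
  if (anyNA(ranks) || any(!is.finite(ranks)))
    stop("ranks must be finite")
  if (any(ranks < 1 - 1e-9) || any(ranks > n + 1e-9))
    stop("ranks must lie in [1, n]")
  out <- rowSums(ranks) / (ncol(ranks) * n)
  names(out) <- rownames(ranks)
  out
}

#' Per-dimension RSR scores of an indicator table
#'
#' Applies [rsr_rank()] to every indicator column (per its orientation) and
#' [rsr_score()] within each dimension. Dimensions are never pooled: each
#' yields its own RSR vector, later graded and combined only through the WHO
#' type map (see [classify_regions()]).
#'
#' @param table an [indicator_table()].
#' @return named list, one element per dimension (in the order they first
#'   appear in the spec table), each a data.frame with columns `unit`, `rsr`
#'   and `rank` (descending competition-style rank of `rsr`, ties averaged),
#'   plus attributes `m` (indicator count) and `dimension`.
#' @examples
#' syn <- synth_indicators(n_units = 8, seed = 1)
#' rsr_dimensions(syn$table)
#' @export
rsr_dimensions <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  specs <- table$specs
  dims <- unique(specs$dimension)
  out <- list()
  for (d in dims) {
    ids <- specs$id[specs$dimension == d]
    ranks <- vapply(ids, function(id) {
      rsr_rank(table$values[, id],
               specs$orientation[specs$id == id])
    }, numeric(nrow(table$values)))
    rsr <- rsr_score(ranks)
    df <- data.frame(unit = table$units,
                     rsr = unname(rsr),
                     rank = rank(-rsr, ties.method = "average"),
                     stringsAsFactors = FALSE)
    attr(df, "m") <- length(ids)
    attr(df, "dimension") <- d
    out[[d]] <- df
  }
  out
}
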