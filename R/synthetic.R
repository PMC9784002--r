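#' Generate a synthetic indicator table with known latent quality
#'
#' Emulates the statistical structure the RSR evaluation assumes: each
#' dimension has one latent per-unit quality score (standard normal by
#' default) and every indicator observes it through an additive Gaussian
#' noise channel, with the sign flipped for low-quality indicators, i.e.
#' `value = latent + noise` for high-quality and `value = -latent + noise`
#' for low-quality columns. With `noise_sd = 0` every indicator is a strictly
#' monotone transform of its dimension's latent quality, so the per-dimension
#' RSR ordering recovers the latent ordering exactly.
#'
#' The default panel mirrors the maternal-services study: 31 units, 12
#' indicators split 3/5/4 across needs/utilization/resources, and one
#' low-quality indicator (the first needs indicator, mirroring the maternal
#' mortality rate).
#'
#' @param n_units number of units (default 31).
#' @param dims named integer vector of per-dimension indicator counts
#'   (default `c(needs = 3, utilization = 5, resources = 4)`).
#' @param noise_sd per-indicator observation noise standard deviation
#'   (scalar or one value per indicator; default 0.1).
#' @param latent_sd standard deviation of the latent quality (default 1).
#' @param low_quality character vector of indicator ids generated as
#'   low-quality (default the first indicator of the first dimension).
#' @param seed optional integer seed for reproducibility.
#' @return list with elements `table` (an [indicator_table()]), `latent`
#'   (`n_units` x `length(dims)` matrix of latent qualities) and `config`.
#' @examples
#' syn <- synth_indicators(seed = 7)
#' syn$table
#' cor(syn$latent[, "needs"],
#'     rsr_dimensions(syn$table)$needs$rsr, method = "spearman")
#' @export
synth_indicators <- function(n_units = 31,
                             dims = c(needs = 3, utilization = 5,
                                      resources = 4),
                             noise_sd = 0.1, latent_sd = 1,
                             low_quality = NULL, seed = NULL) {
  if (n_units < 2L) stop("n_units must be >= 2")
  if (any(dims < 1L)) stop("every dimension needs >= 1 indicator")
  if (is.null(names(dims)) || anyDuplicated(names(dims)))
    stop("dims must have unique dimension names")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  m <- sum(dims)
  ids <- paste0("X", seq_len(m))
  dimension <- rep(names(dims), dims)
  if (is.null(low_quality)) low_quality <- ids[1]
  if (!all(low_quality %in% ids))
    stop("low_quality ids not in panel: ",
         paste(setdiff(low_quality, ids), collapse = ", "))
  orientation <- ifelse(ids %in% low_quality, "low_quality", "high_quality")
  noise_sd <- rep_len(noise_sd, m)

  latent <- matrix(rnorm(n_units * length(dims), sd = latent_sd),
                   n_units, length(dims),
                   dimnames = list(NULL, names(dims)))
  values <- matrix(0, n_units, m, dimnames = list(NULL, ids))
  for (j in seq_len(m)) {
    sgn <- if (orientation[j] == "low_quality") -1 else 1
    values[, j] <- sgn * latent[, dimension[j]] +
      rnorm(n_units, sd = noise_sd[j])
  }
  units <- sprintf("unit%02d", seq_len(n_units))
  rownames(values) <- units
  rownames(latent) <- units
  specs <- data.frame(id = ids, name = ids, dimension = dimension,
                      orientation = orientation, stringsAsFactors = FALSE)
  list(table = indicator_table(values, specs, units = units),
       latent = latent,
       config = list(n_units = n_units, dims = dims, noise_sd = noise_sd,
                     latent_sd = latent_sd, low_quality = low_quality,
                     seed = seed))
}

#' Generate an RSR-like vector
#'
#' Draws `n` values uniformly from `[1/n, 1]` (the attainable RSR range),
#' optionally forcing a number of exact ties for tie-handling tests.
#'
#' @param n length (>= 2).
#' @param seed optional integer seed.
#' @param n_ties number of values made exactly equal to another value
#'   (default 0).
#' @return named numeric vector of length `n` in `[1/n, 1]`.
#' @examples
#' v <- synth_rsr(31, seed = 1, n_ties = 2)
#' sum(duplicated(v))  # 2
#' @export
synth_rsr <- function(n, seed = NULL, n_ties = 0) {
  if (n < 2L) stop("n must be >= 2")
  if (n_ties > n - 1L) stop("n_ties must be < n")
  if (!is.null(seed)) set.seed(seed)
  v <- runif(n, min = 1 / n, max = 1)
  if (n_ties > 0) {
    idx <- sample(seq_len(n), n_ties)
    src <- sample(setdiff(seq_len(n), idx), n_ties, replace = TRUE)
    v[idx] <- v[src]
  }
  setNames(v, sprintf("unit%02d", seq_len(n)))
}
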