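#' Packaged provincial maternal-services evaluation tables (2009, 2019)
#'
#' The printed per-province results of the Chinese maternal-services
#' evaluation panel (31 provinces, municipalities and autonomous regions;
#' three dimensions: needs, utilization, resource allocation), stored as
#' plain-text CSV at the published precision:
#' \describe{
#'   \item{`"rsr"`}{per-province RSR score (3 decimals) and published
#'     descending rank, per dimension.}
#'   \item{`"probit"`}{per-province downward cumulative frequency `p`
#'     (percent, 1 decimal) and probit (3 decimals), per dimension.}
#'   \item{`"grading"`}{per-province Low/Medium/High grade and fitted RSR
#'     from the published grading tables.}
#' }
#' The two homonymous provinces are stored under the distinct romanizations
#' `"Shanxi"` and `"Shaanxi"`. Published RSR values are rounded to 3
#' decimals, so a few provinces tie exactly in the fixture although their
#' unrounded values differed; the published ranks are preserved verbatim
#' (the known 2009 needs 0.253/0.253 tie keeps its distinct printed ranks).
#'
#' @param year 2009 or 2019.
#' @param table `"rsr"`, `"probit"` or `"grading"`.
#' @return a data.frame in the published province order: for `"rsr"` columns
#'   `region`, `dimension`, `rsr`, `rank`; for `"probit"` columns `region`,
#'   `dimension`, `p`, `probit`; for `"grading"` columns `region`,
#'   `dimension`, `grade`, `fitted_rsr`.
#' @seealso [maternal_rsr()] for one dimension as a named vector.
#' @examples
#' head(maternal_fixture(2009, "rsr"))
#' @export
maternal_fixture <- function(year, table = c("rsr", "probit", "grading")) {
  table <- match.arg(table)
  year <- as.character(year)
  if (!year %in% c("2009", "2019"))
    stop("year must be 2009 or 2019, got ", year)
  file <- c(rsr = "maternal_rsr.csv", probit = "maternal_probit.csv",
            grading = "maternal_grading.csv")[table]
  path <- system.file("extdata", file, package = "rsreval", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- df[df$year == year, setdiff(names(df), "year"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' One fixture dimension as a named RSR vector
#'
#' @param year 2009 or 2019.
#' @param dimension `"needs"`, `"utilization"` or `"resources"`.
#' @return named numeric vector of 31 RSR values in province order.
#' @examples
#' maternal_rsr(2009, "utilization")[["Beijing"]]  # 0.814
#' @export
maternal_rsr <- function(year,
                         dimension = c("needs", "utilization", "resources")) {
  dimension <- match.arg(dimension)
  df <- maternal_fixture(year, "rsr")
  df <- df[df$dimension == dimension, ]
  setNames(df$rsr, df$region)
}
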