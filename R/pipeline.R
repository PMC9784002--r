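#' Run the full RSR comprehensive-evaluation pipeline
#'
#' From raw indicators (or a packaged fixture year) to classification: ranks
#' each dimension's indicators ([rsr_rank()]), computes per-dimension RSR
#' scores ([rsr_score()]), fits the RSR~probit grading line per dimension
#' ([rsr_fit()]), and classifies every region into a WHO type and policy
#' category ([classify_regions()]).
#'
#' @param x an [indicator_table()]; or `2009`/`2019` to run on the packaged
#'   provincial maternal-services RSR fixtures; or a named list of per-
#'   dimension RSR vectors with elements `needs`, `utilization`, `resources`.
#' @param cuts probit cut-offs, default `c(4, 6)`.
#' @param ties tie handling for [rsr_probit()] (`"average"` default).
#' @return an object of class `rsr_evaluation`: list with `fits` (named list
#'   of [rsr_fit()] per dimension), `classification`
#'   (a [classify_regions()] result), `counts`, and `year` (label or `NULL`).
#' @examples
#' ev <- rsr_evaluate(2009)
#' ev$counts          # 16, 3, 3, 5, 4
#' ev$fits$needs      # grading line, critical values, grade sizes
#' @export
rsr_evaluate <- function(x, cuts = c(4, 6), ties = c("average", "first")) {
  ties <- match.arg(ties)
  year <- NULL
  if (inherits(x, "indicator_table")) {
    dims <- rsr_dimensions(x)
    vecs <- lapply(dims, function(d) setNames(d$rsr, d$unit))
  } else if (length(x) == 1L && as.character(x) %in% c("2009", "2019")) {
    year <- as.character(x)
    vecs <- lapply(c(needs = "needs", utilization = "utilization",
                     resources = "resources"),
                   function(d) maternal_rsr(year, d))
  } else if (is.list(x)) {
    need <- c("needs", "utilization", "resources")
    if (!all(need %in% names(x)))
      stop("RSR list must have elements: ", paste(need, collapse = ", "))
    vecs <- x[need]
  } else {
    stop("x must be an indicator_table, a fixture year (2009/2019), ",
         "or a named list of RSR vectors")
  }
  fits <- lapply(vecs, rsr_fit, cuts = cuts, ties = ties)
  if (length(cuts) != 2L)
    stop("classification requires the three-grading scheme (2 cuts)")
  cls <- classify_regions(fits$needs, fits$utilization, fits$resources,
                          year = year)
  structure(list(fits = fits, classification = cls,
                 counts = category_counts(cls), year = year,
                 cuts = cuts, ties = ties),
            class = "rsr_evaluation")
}

#' @export
print.rsr_evaluation <- function(x, ...) {
  cat("RSR comprehensive evaluation",
      if (!is.null(x$year)) paste0(" (", x$year, ")"), "\n", sep = "")
  for (d in names(x$fits)) {
    f <- x$fits[[d]]
    cat(sprintf("  %-12s RSR-hat = %.3f x probit %+.3f  (adj R2 = %.3f)\n",
                d, f$b, f$a, f$r_adj))
  }
  cat("  category counts:\n")
  print(x$counts)
  invisible(x)
}

#' @export
summary.rsr_evaluation <- function(object, ...) {
  structure(list(ev = object,
                 validation = lapply(object$fits, validate_grades)),
            class = "summary.rsr_evaluation")
}

#' @export
print.summary.rsr_evaluation <- function(x, ...) {
  print(x$ev)
  for (d in names(x$validation)) {
    cat("\n== ", d, " ==\n", sep = "")
    print(x$validation[[d]])
  }
  invisible(x)
}

#' @export
plot.rsr_evaluation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$fits)))
  on.exit(graphics::par(op))
  for (d in names(x$fits)) plot(x$fits[[d]], main = d)
  invisible(x)
}

#' Write an evaluation report bundle
#'
#' Writes, per dimension, the RSR table (score and descending rank), the
#' distribution table (P and probit), and the grading table (grade, fitted
#' RSR, line coefficients and critical values in the header comment), plus
#' the classification table and category counts. CSV output rounds to 3
#' decimals (published precision); JSON keeps full precision. Rows are
#' ordered by unit id so repeated runs are byte-identical.
#'
#' @param ev an [rsr_evaluate()] result.
#' @param dir output directory (created if needed).
#' @param format `"csv"`, `"json"`, or both.
#' @return invisibly, the paths written.
#' @export
write_rsr_report <- function(ev, dir, format = c("csv", "json")) {
  stopifnot(inherits(ev, "rsr_evaluation"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  rsr_tab <- do.call(rbind, lapply(names(ev$fits), function(d) {
    f <- ev$fits[[d]]
    data.frame(unit = f$dist$unit, dimension = d, rsr = f$dist$rsr,
               rank = rank(-f$dist$rsr, ties.method = "average"),
               p = f$dist$p, probit = f$dist$probit,
               fitted_rsr = unname(f$fitted_rsr),
               grade = as.character(f$grade), stringsAsFactors = FALSE)
  }))
  rsr_tab <- rsr_tab[order(rsr_tab$dimension, rsr_tab$unit), ]
  fit_tab <- do.call(rbind, lapply(names(ev$fits), function(d) {
    f <- ev$fits[[d]]
    data.frame(dimension = d, a = f$a, b = f$b, r = f$r, r_adj = f$r_adj,
               p_value = f$p_value,
               critical_low = f$critical_rsr[1],
               critical_high = f$critical_rsr[2], stringsAsFactors = FALSE)
  }))
  cls <- as.data.frame(ev$classification)
  cls <- cls[order(cls$unit), ]
  counts <- data.frame(category = names(ev$counts),
                       count = as.integer(ev$counts),
                       stringsAsFactors = FALSE)

  if ("csv" %in% format) {
    num <- function(df) {
      for (j in seq_along(df)) if (is.double(df[[j]]))
        df[[j]] <- sprintf("%.3f", df[[j]])
      df
    }
    for (nm in c("evaluation", "fit", "classification", "counts")) {
      obj <- switch(nm, evaluation = num(rsr_tab), fit = num(fit_tab),
                    classification = cls, counts = counts)
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(obj, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(year = ev$year, cuts = ev$cuts, ties = ev$ties,
           fits = fit_tab, evaluation = rsr_tab,
           classification = cls, counts = counts),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
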