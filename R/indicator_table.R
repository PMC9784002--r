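#' Indicator table: regions by indicators, with dimension and orientation
#'
#' The raw input of the evaluation: an `n x m` matrix of finite indicator
#' values together with a specification assigning each indicator to one
#' dimension (`needs`, `utilization`, `resources`) and one orientation
#' (`high_quality`: larger is better; `low_quality`: larger is worse).
#'
#' @param values numeric matrix or data.frame, `n` units x `m` indicators;
#'   column names must match `specs$id`.
#' @param specs data.frame with columns `id`, `name`, `dimension`,
#'   `orientation`.
#' @param units character vector of `n` unique unit identifiers (defaults to
#'   rownames of `values`).
#' @return an object of class `indicator_table`: a list with elements
#'   `units`, `specs`, `values` (matrix with units as rownames).
#' @seealso [read_indicator_table()], [maternal_panel()], [synth_indicators()]
#' @export
indicator_table <- function(values, specs, units = rownames(values)) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  req <- c("id", "name", "dimension", "orientation")
  if (!all(req %in% names(specs)))
    stop("spec must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(specs$id))
    stop("duplicate indicator id in spec: ",
         paste(unique(specs$id[duplicated(specs$id)]), collapse = ", "))
  bad <- setdiff(specs$dimension, c("needs", "utilization", "resources"))
  if (length(bad))
    stop("unknown dimension label: ", paste(bad, collapse = ", "))
  bad <- setdiff(specs$orientation, c("high_quality", "low_quality"))
  if (length(bad))
    stop("unknown orientation: ", paste(bad, collapse = ", "))

  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(units)) stop("unit identifiers are required")
  units <- as.character(units)
  if (nrow(values) != length(units))
    stop("values has ", nrow(values), " rows but ", length(units), " units")
  if (nrow(values) < 2L) stop("need at least 2 units, got ", nrow(values))
  if (anyDuplicated(units))
    stop("duplicate unit id: ",
         paste(unique(units[duplicated(units)]), collapse = ", "),
         " (homonymous regions must carry distinct identifiers)")
  if (is.null(colnames(values)))
    stop("values must have indicator ids as column names")
  unknown <- setdiff(colnames(values), specs$id)
  if (length(unknown))
    stop("indicator id not in spec: ", paste(unknown, collapse = ", "))
  missing_col <- setdiff(specs$id, colnames(values))
  if (length(missing_col))
    stop("spec indicator missing from table: ",
         paste(missing_col, collapse = ", "))
  values <- values[, specs$id, drop = FALSE]
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)[1, ]
    stop("missing or non-finite value at unit '", units[idx[1]],
         "', indicator '", colnames(values)[idx[2]], "'")
  }
  rownames(values) <- units
  structure(list(units = units, specs = specs, values = values),
            class = "indicator_table")
}

#' @export
print.indicator_table <- function(x, ...) {
  tab <- table(x$specs$dimension)
  cat("Indicator table: ", length(x$units), " units x ",
      nrow(x$specs), " indicators (",
      paste(names(tab), tab, sep = " ", collapse = ", "), ")\n", sep = "")
  nlow <- sum(x$specs$orientation == "low_quality")
  cat("  low-quality indicators: ", nlow, "\n", sep = "")
  invisible(x)
}

#' Read an indicator table from CSV
#'
#' The indicators file must have a header row, a first column of unit
#' identifiers and one column per indicator id. The spec file (CSV or JSON)
#' defines `id`, `name`, `dimension` and `orientation` per indicator.
#'
#' @param path path to the indicators CSV.
#' @param spec_path path to the spec CSV or JSON.
#' @return an [indicator_table()].
#' @export
read_indicator_table <- function(path, spec_path) {
  if (!file.exists(path)) stop("indicator file not found: ", path)
  if (!file.exists(spec_path)) stop("spec file not found: ", spec_path)
  if (grepl("\\.json$", spec_path, ignore.case = TRUE)) {
    specs <- as.data.frame(jsonlite::fromJSON(spec_path),
                           stringsAsFactors = FALSE)
  } else {
    specs <- read.csv(spec_path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 encoding = "UTF-8")
  if (ncol(df) < 2L) stop("indicators CSV needs a unit column plus indicators: ", path)
  units <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      blank <- is.na(v) | !nzchar(trimws(v))
      if (any(blank))
        stop("empty cell at unit '", units[which(blank)[1]], "', indicator '",
             names(vals)[j], "' in ", path)
      vals[[j]] <- as.numeric(v)
    }
    if (anyNA(vals[[j]]))
      stop("missing value at unit '", units[which(is.na(vals[[j]]))[1]],
           "', indicator '", names(vals)[j], "' in ", path)
  }
  indicator_table(as.matrix(vals), specs, units = units)
}

#' Write an indicator table to CSV
#'
#' Writes the values (with the unit id as first column, full precision) and,
#' optionally, the spec. `read_indicator_table()` on the written files is the
#' identity on values.
#'
#' @param x an [indicator_table()].
#' @param path output path for the indicators CSV.
#' @param spec_path optional output path for the spec CSV.
#' @return `x`, invisibly.
#' @export
write_indicator_table <- function(x, path, spec_path = NULL) {
  stopifnot(inherits(x, "indicator_table"))
  df <- data.frame(unit = x$units, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(spec_path))
    write.csv(x$specs, spec_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' The 12-indicator maternal-services panel specification
#'
#' Three needs indicators (X1-X3: maternal mortality rate, proportion of
#' obstetric hemorrhage in maternal deaths, proportion of pregnancy-induced
#' hypertension in maternal deaths), five utilization indicators (X4-X8:
#' registration, system management, prenatal checkup, postpartum visit and
#' hospital delivery rates) and four resource-allocation indicators (X9-X12:
#' medical institutions, practicing physicians, registered nurses, obstetrics
#' and gynecology beds per population). The maternal mortality rate is the
#' single low-quality indicator; all others are high-quality.
#'
#' @return a data.frame with columns `id`, `name`, `dimension`, `orientation`.
#' @export
maternal_panel <- function() {
  data.frame(
    id = paste0("X", 1:12),
    name = c("maternal mortality rate (1/100,000)",
             "proportion of obstetric hemorrhage in maternal deaths (%)",
             "proportion of pregnancy-induced hypertension in maternal deaths (%)",
             "registration rate (%)",
             "system management rate (%)",
             "prenatal checkup rate (%)",
             "postpartum visit rate (%)",
             "hospital delivery rate (%)",
             "medical institutions (1/100,000)",
             "practicing (assistant) physicians (1/1,000)",
             "registered nurses (1/1,000)",
             "obstetrics and gynecology beds (1/100,000)"),
    dimension = rep(c("needs", "utilization", "resources"), c(3, 5, 4)),
    orientation = c("low_quality", rep("high_quality", 11)),
    stringsAsFactors = FALSE
  )
}
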