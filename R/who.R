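#' WHO comprehensive-evaluation type from a two-level grade triple
#'
#' The original WHO cross-classification of health-service needs, utilization
#' and resource input at two levels each: with grades (needs, utilization,
#' resources) written as H/L, (H,H,H) is type A, (H,H,L) B, (H,L,H) C,
#' (H,L,L) D, (L,H,H) E, (L,H,L) F, (L,L,H) G and (L,L,L) H. Types A and H
#' indicate appropriate resource allocation, B and F high utilization, C and
#' E low and over utilization, D and G low and over investment.
#'
#' @param needs,utilization,resources character vectors of grades, `"Low"` or
#'   `"High"` (recycled to a common length).
#' @return character vector of types `"A"`..`"H"`.
#' @examples
#' who_type_2level("High", "High", "High")  # "A"
#' who_type_2level("Low", "Low", "Low")     # "H"
#' @export
who_type_2level <- function(needs, utilization, resources) {
  k <- check_grades(needs, utilization, resources, c("Low", "High"))
  # order: needs, utilization, resources
  key <- paste(k$needs, k$utilization, k$resources, sep = "|")
  map <- c("High|High|High" = "A", "High|High|Low" = "B",
           "High|Low|High" = "C", "High|Low|Low" = "D",
           "Low|High|High" = "E", "Low|High|Low" = "F",
           "Low|Low|High" = "G", "Low|Low|Low" = "H")
  unname(map[key])
}

#' WHO comprehensive-evaluation type from a three-level grade triple
#'
#' The China extension of the WHO model to three levels per axis (27 cells),
#' used for grading public-health services with the RSR method. The map is
#' shipped as editable JSON in `extdata/who_map_3level.json` (keys
#' `"utilization|needs|resources"`); restricted to `Low`/`High` grades it
#' coincides with [who_type_2level()].
#'
#' @inheritParams who_type_2level
#' @return character vector of types `"A"`..`"H"`.
#' @examples
#' who_type_3level("Medium", "Medium", "Medium")  # "A": balanced
#' who_type_3level("Low", "High", "High")         # "E": overutilization
#' @export
who_type_3level <- function(needs, utilization, resources) {
  k <- check_grades(needs, utilization, resources, c("Low", "Medium", "High"))
  map <- who_map_3level()
  key <- paste(k$utilization, k$needs, k$resources, sep = "|")
  out <- map[key]
  if (anyNA(out)) stop("grade triple not covered by the 3-level map: ",
                       paste(key[is.na(out)], collapse = ", "))
  unname(out)
}

check_grades <- function(needs, utilization, resources, allowed) {
  n <- max(length(needs), length(utilization), length(resources))
  k <- list(needs = rep_len(as.character(needs), n),
            utilization = rep_len(as.character(utilization), n),
            resources = rep_len(as.character(resources), n))
  bad <- setdiff(unique(unlist(k)), allowed)
  if (length(bad))
    stop("invalid grade label(s) for this mode: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  k
}

who_map_3level <- function() {
  if (is.null(.rsreval_env$map3)) {
    path <- system.file("extdata", "who_map_3level.json", package = "rsreval",
                        mustWork = TRUE)
    m <- unlist(jsonlite::fromJSON(path))
    if (length(m) != 27L || !all(m %in% LETTERS[1:8]))
      stop("malformed 3-level WHO map at ", path)
    .rsreval_env$map3 <- m
  }
  .rsreval_env$map3
}

#' Policy category of a WHO type
#'
#' Groups the eight types into five policy categories: relative balance
#' (A, H, F), low input (B), resource shortage (D), overutilization (E) and
#' resource waste (C, G).
#'
#' @param type character vector of types `"A"`..`"H"`.
#' @return character vector of category labels.
#' @examples
#' who_category(c("A", "D", "C"))
#' @export
who_category <- function(type) {
  map <- c(A = "relative_balance", H = "relative_balance",
           F = "relative_balance", B = "low_input",
           D = "resource_shortage", E = "overutilization",
           C = "resource_waste", G = "resource_waste")
  bad <- setdiff(unique(type), names(map))
  if (length(bad)) stop("unknown WHO type: ", paste(bad, collapse = ", "))
  unname(map[as.character(type)])
}

#' The five policy-category labels, in reporting order
#' @return character vector of length 5.
#' @export
policy_categories <- function() {
  c("relative_balance", "low_input", "resource_shortage",
    "overutilization", "resource_waste")
}

#' Classify regions from three per-dimension grading fits
#'
#' Combines the Low/Medium/High grades of the needs, utilization and
#' resource-allocation dimensions into a per-region WHO type (27-cell map)
#' and policy category.
#'
#' @param needs,utilization,resources [rsr_fit()] objects (or named grade
#'   vectors) for the three dimensions, covering identical unit sets.
#' @param year optional label attached to the result.
#' @return an object of class `who_classification`: a data.frame with columns
#'   `unit`, `needs`, `utilization`, `resources`, `type`, `category`, plus
#'   attributes `counts` (per-category, in [policy_categories()] order) and
#'   `year`.
#' @examples
#' ev <- rsr_evaluate(2009)
#' ev$classification
#' @export
classify_regions <- function(needs, utilization, resources, year = NULL) {
  g <- lapply(list(needs = needs, utilization = utilization,
                   resources = resources), function(x) {
    if (inherits(x, "rsr_fit")) setNames(as.character(x$grade), names(x$grade))
    else setNames(as.character(x), names(x))
  })
  units <- names(g$needs)
  if (is.null(units)) stop("grades must be named by unit")
  for (d in c("utilization", "resources")) {
    if (!setequal(units, names(g[[d]])))
      stop("unit sets differ between needs and ", d, ": ",
           paste(union(setdiff(units, names(g[[d]])),
                       setdiff(names(g[[d]]), units)), collapse = ", "))
    g[[d]] <- g[[d]][units]
  }
  type <- who_type_3level(g$needs, g$utilization, g$resources)
  category <- who_category(type)
  out <- data.frame(unit = units, needs = unname(g$needs),
                    utilization = unname(g$utilization),
                    resources = unname(g$resources),
                    type = type, category = category,
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$category, levels = policy_categories()))
  attr(out, "counts") <- counts
  attr(out, "year") <- year
  class(out) <- c("who_classification", "data.frame")
  out
}

#' @export
print.who_classification <- function(x, ...) {
  yr <- attr(x, "year")
  cat("WHO classification", if (!is.null(yr)) paste0(" (", yr, ")"),
      ": ", nrow(x), " regions\n", sep = "")
  print(attr(x, "counts"))
  invisible(x)
}

#' Category counts of a classification
#'
#' @param x a [classify_regions()] result.
#' @return named integer vector over [policy_categories()].
#' @export
category_counts <- function(x) {
  stopifnot(inherits(x, "who_classification"))
  c(attr(x, "counts"))
}

#' Category transitions between two classifications
#'
#' Cross-tabulates each region's policy category at two time points. No
#' ordering of categories ("improvement") is imposed; transitions are
#' reported descriptively.
#'
#' @param earlier,later [classify_regions()] results over the same unit set.
#' @return an object of class `who_transitions`: list with `matrix` (5x5
#'   category transition counts, rows = earlier), `moves` (data.frame of
#'   units that changed category: `unit`, `from`, `to`), and `into_balance`
#'   (count of units moving from a non-balance category into
#'   `relative_balance`).
#' @examples
#' tr <- transitions(rsr_evaluate(2009)$classification,
#'                   rsr_evaluate(2019)$classification)
#' tr$into_balance   # 8
#' @export
transitions <- function(earlier, later) {
  stopifnot(inherits(earlier, "who_classification"),
            inherits(later, "who_classification"))
  if (!setequal(earlier$unit, later$unit))
    stop("unit sets differ: ",
         paste(union(setdiff(earlier$unit, later$unit),
                     setdiff(later$unit, earlier$unit)), collapse = ", "))
  later <- later[match(earlier$unit, later$unit), ]
  lv <- policy_categories()
  m <- table(factor(earlier$category, lv), factor(later$category, lv),
             dnn = c("earlier", "later"))
  changed <- earlier$category != later$category
  moves <- data.frame(unit = earlier$unit[changed],
                      from = earlier$category[changed],
                      to = later$category[changed],
                      stringsAsFactors = FALSE)
  structure(list(
    matrix = m,
    moves = moves,
    into_balance = sum(earlier$category != "relative_balance" &
                         later$category == "relative_balance")
  ), class = "who_transitions")
}

#' @export
print.who_transitions <- function(x, ...) {
  cat("Category transitions (", nrow(x$moves), " regions changed; ",
      x$into_balance, " moved into relative_balance)\n", sep = "")
  print(x$matrix)
  invisible(x)
}
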