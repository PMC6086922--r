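#' Construct a strain table
#'
#' A strain table is the fundamental input of the model: one row per strain,
#' with the three growth traits that define its growth curve. `lag` is the
#' lag time \eqn{\lambda} (no growth after resource renewal), `growth_time`
#' is the exponential growth time \eqn{\tau} (reciprocal growth rate; time
#' for an e-fold increase), and `yield` is \eqn{Y}, the number of cells
#' supported per unit resource. Time and resource units are arbitrary but
#' must be consistent across strains.
#'
#' @param label Character vector of unique strain labels.
#' @param lag Numeric vector of lag times, `>= 0`.
#' @param growth_time Numeric vector of exponential growth times, `> 0`.
#' @param yield Numeric vector of yields (cells per resource unit), `> 0`.
#'
#' @return A `data.frame` of class `strain_table` with columns
#'   `label`, `lag`, `growth_time`, `yield`.
#' @examples
#' strain_table(c("A", "B"), lag = c(1, 2), growth_time = c(1, 0.8),
#'              yield = c(1e5, 2e5))
#' @export
strain_table <- function(label, lag, growth_time, yield) {
  st <- data.frame(label = as.character(label), lag = as.numeric(lag),
                   growth_time = as.numeric(growth_time),
                   yield = as.numeric(yield), stringsAsFactors = FALSE)
  class(st) <- c("strain_table", "data.frame")
  validate_strains(st)
  st
}

#' Validate a strain table
#'
#' Checks trait invariants: finite traits, `lag >= 0`, `growth_time > 0`,
#' `yield > 0`, and unique labels. Called by every operation that accepts
#' strains; exported so user code can validate tables read from elsewhere.
#'
#' @param strains A data frame with columns `label`, `lag`, `growth_time`,
#'   `yield`.
#' @return `strains`, invisibly, with class `strain_table` ensured.
#' @export
validate_strains <- function(strains) {
  required <- c("label", "lag", "growth_time", "yield")
  if (!is.data.frame(strains) || !all(required %in% names(strains)))
    sc_error("strains must be a data frame with columns label, lag, growth_time, yield",
             "validation")
  if (nrow(strains) < 1L)
    sc_error("strain table is empty", "validation")
  num <- c("lag", "growth_time", "yield")
  for (col in num) {
    v <- strains[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      sc_error(sprintf("column '%s' must be finite numeric", col), "validation")
  }
  if (any(strains$lag < 0))
    sc_error("lag times must be >= 0", "validation")
  if (any(strains$growth_time <= 0))
    sc_error("growth times must be > 0", "validation")
  if (any(strains$yield <= 0))
    sc_error("yields must be > 0", "validation")
  if (anyDuplicated(strains$label))
    sc_error("strain labels must be unique", "validation")
  if (!inherits(strains, "strain_table"))
    class(strains) <- c("strain_table", class(strains))
  invisible(strains)
}

#' Validate a density vector against a strain table
#'
#' Densities are population fractions at the start of a competition round:
#' non-negative and summing to one. Unnamed vectors are matched by position;
#' named vectors are reordered to match the strain labels.
#'
#' @param x Numeric vector of densities.
#' @param strains Strain table the densities refer to.
#' @param tol Tolerance on the simplex-sum constraint.
#' @return Densities as a numeric vector aligned with `strains`.
#' @export
validate_densities <- function(x, strains, tol = 1e-9) {
  if (!is.null(names(x))) {
    if (!setequal(names(x), strains$label))
      sc_error("density names do not match strain labels", "validation")
    x <- x[strains$label]
  }
  x <- as.numeric(x)
  if (length(x) != nrow(strains))
    sc_error("densities must have one entry per strain", "validation")
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    sc_error("densities must be finite and non-negative", "validation")
  if (abs(sum(x) - 1) > tol)
    sc_error(sprintf("densities must sum to 1 (got %.12g)", sum(x)), "validation")
  x / sum(x)
}

#' Uniform initial densities
#'
#' @param strains Strain table.
#' @return Vector `1/M` for each of the `M` strains, named by label.
#' @export
uniform_densities <- function(strains) {
  m <- nrow(strains)
  stats::setNames(rep(1 / m, m), strains$label)
}

#' Read a strain table from delimited text
#'
#' Strict CSV/TSV reader: the header must be exactly
#' `label,lag,growth_time,yield` (any order is rejected), decimal points only,
#' no missing fields. Malformed rows are reported by row number.
#'
#' @param path Path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param sep Field separator, default comma.
#' @return A validated [strain_table()].
#' @export
read_strain_table <- function(path, sep = ",") {
  if (!file.exists(path))
    sc_error(sprintf("strain table not found: %s", path), "io")
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("label", "lag", "growth_time", "yield")))
    sc_error("strain table header must be exactly: label,lag,growth_time,yield",
             "parse")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "character", "character",
                                         "character"),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  parse_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) | grepl(",", v, fixed = TRUE))
    if (length(bad))
      sc_error(sprintf("malformed numeric in column '%s', row %d", col, bad[1]),
               "parse")
    out
  }
  st <- data.frame(label = df$label,
                   lag = parse_num(df$lag, "lag"),
                   growth_time = parse_num(df$growth_time, "growth_time"),
                   yield = parse_num(df$yield, "yield"),
                   stringsAsFactors = FALSE)
  bad <- which(st$growth_time <= 0 | st$yield <= 0 | st$lag < 0)
  if (length(bad))
    sc_error(sprintf("invalid trait values in row %d", bad[1]), "parse")
  if (anyDuplicated(st$label))
    sc_error(sprintf("duplicate strain label '%s'",
                     st$label[anyDuplicated(st$label)]), "parse")
  class(st) <- c("strain_table", "data.frame")
  st
}

#' Write a strain table to CSV
#'
#' Inverse of [read_strain_table()]; full double precision so that a
#' write-read round trip is the identity.
#'
#' @param strains Strain table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(strains, path) {
  validate_strains(strains)
  out <- data.frame(label = strains$label,
                    lag = format(strains$lag, digits = 17, trim = TRUE),
                    growth_time = format(strains$growth_time, digits = 17,
                                         trim = TRUE),
                    yield = format(strains$yield, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Condition constructor shared across the package: every error carries a
# subclass "serialcoex_<class>_error" so callers can branch on failure mode.
sc_error <- function(msg, class) {
  stop(structure(class = c(sprintf("serialcoex_%s_error", class),
                           "serialcoex_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
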