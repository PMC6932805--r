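#' Read a long-format yield-trial table
#'
#' Reads a plain CSV (RFC-4180, UTF-8, header row required) holding one row
#' per variety x site x year with the mean plot yield in Mg/ha, and returns a
#' validated trial data frame with the canonical columns `variety`, `site`,
#' `year`, `yield` and, when present in the file, `region` and `is_check`.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping canonical column names to
#'   the file's header names, e.g. `c(variety = "hybrid", yield = "yld")`.
#'   Canonical names absent from the map are looked up verbatim. `region` and
#'   `is_check` are optional.
#' @return A `data.frame` of trial records, one per (variety, site, year).
#' @details Yields must parse as non-negative finite decimals (`.` separator;
#'   thousands separators are rejected). Duplicate (variety, site, year) keys
#'   are an error: the input unit is already the mean over replicates.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(hybrid = "A", loc = "N1", yr = 2001, yld = 10.2),
#'           tf, row.names = FALSE)
#' read_trials(tf, c(variety = "hybrid", site = "loc", year = "yr", yield = "yld"))
#' @seealso [filter_trials()], [write_trials()]
#' @export
read_trials <- function(path, column_map = character()) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  canon <- c("variety", "site", "year", "yield", "region", "is_check")
  required <- canon[1:4]
  map <- setNames(canon, canon)
  if (length(column_map)) {
    bad <- setdiff(names(column_map), canon)
    if (length(bad)) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  missing_req <- required[!map[required] %in% names(raw)]
  if (length(missing_req)) {
    stop("mapped column(s) missing from header of ", path, ": ",
         paste(sprintf("%s (expected '%s')", missing_req, map[missing_req]),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    variety = raw[[map["variety"]]],
    site    = raw[[map["site"]]],
    year    = raw[[map["year"]]],
    yield   = raw[[map["yield"]]],
    stringsAsFactors = FALSE
  )
  if (map["region"] %in% names(raw))   out$region   <- raw[[map["region"]]]
  if (map["is_check"] %in% names(raw)) out$is_check <- raw[[map["is_check"]]]
  if (nrow(out) == 0L) return(validate_trials(out[0, , drop = FALSE]))

  out$year <- parse_strict_numeric(out$year, "year", path)
  if (any(out$year != round(out$year))) {
    i <- which(out$year != round(out$year))[1L]
    stop(sprintf("non-integer year '%s' at data row %d of %s",
                 raw[[map["year"]]][i], i, path), call. = FALSE)
  }
  out$year <- as.integer(out$year)
  out$yield <- parse_strict_numeric(out$yield, "yield", path)
  if (!is.null(out$is_check)) out$is_check <- parse_logical(out$is_check, path)
  validate_trials(out)
}

parse_strict_numeric <- function(x, what, path) {
  ok <- grepl("^\\s*-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?\\s*$", x)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop(sprintf("non-numeric %s '%s' at data row %d of %s", what, x[i], i, path),
         call. = FALSE)
  }
  as.numeric(x)
}

parse_logical <- function(x, path) {
  lx <- tolower(trimws(x))
  val <- rep(NA, length(x))
  val[lx %in% c("true", "t", "1", "yes")] <- TRUE
  val[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(val) && length(x)) {
    i <- which(is.na(val))[1L]
    stop(sprintf("unparseable is_check value '%s' at data row %d of %s",
                 x[i], i, path), call. = FALSE)
  }
  as.logical(val)
}

#' Validate a trial data frame
#'
#' Checks the invariants assumed by every downstream step: canonical columns
#' present, finite non-negative yields, integer years, and a unique
#' (variety, site, year) key.
#'
#' @param trials A data frame with columns `variety`, `site`, `year`, `yield`.
#' @return The input, invisibly coerced to canonical types.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("trials must be a data frame", call. = FALSE)
  need <- c("variety", "site", "year", "yield")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trials$variety <- as.character(trials$variety)
  trials$site <- as.character(trials$site)
  trials$year <- as.integer(trials$year)
  trials$yield <- as.numeric(trials$yield)
  if (nrow(trials)) {
    if (anyNA(trials$year)) stop("missing year values", call. = FALSE)
    bad <- !is.finite(trials$yield) | trials$yield < 0
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("yield must be finite and >= 0; offending record (%s, %s, %d)",
                   trials$variety[i], trials$site[i], trials$year[i]),
           call. = FALSE)
    }
    key <- paste(trials$variety, trials$site, trials$year, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1L]
      stop(sprintf("duplicate (variety, site, year) key: (%s, %s, %d)",
                   trials$variety[i], trials$site[i], trials$year[i]),
           call. = FALSE)
    }
  }
  rownames(trials) <- NULL
  trials
}

#' Write a trial table to CSV
#'
#' Companion to [read_trials()]: emits the canonical long CSV so that a
#' read-write-read roundtrip preserves every record.
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  write.csv(trials, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Inclusion rules for trial records
#'
#' Constructs the filter applied by [filter_trials()]. The defaults keep
#' everything except sites observed in fewer than four distinct years, the
#' criterion used to restrict a trial network to consistently represented
#' locations ("represented in more than three years").
#'
#' @param checks_only Keep only check (control) varieties? Requires an
#'   `is_check` column; if the column is absent an error is raised rather
#'   than guessing. When `FALSE`, rows without the column are treated as
#'   checks.
#' @param exclude_years Integer vector of calendar years to drop outright
#'   (e.g. years with too few checks to anchor comparisons).
#' @param min_checks_per_cell Minimum number of distinct varieties a
#'   (site, year) cell must hold; smaller cells are dropped whole.
#' @param min_years_per_site Minimum number of distinct years a site must be
#'   observed in; sites below it are dropped whole.
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(checks_only = FALSE, exclude_years = integer(0),
                         min_checks_per_cell = 0L, min_years_per_site = 4L) {
  stopifnot(is.logical(checks_only), length(checks_only) == 1L)
  exclude_years <- as.integer(exclude_years)
  min_checks_per_cell <- as.integer(min_checks_per_cell)
  min_years_per_site <- as.integer(min_years_per_site)
  if (min_checks_per_cell < 0L || min_years_per_site < 0L) {
    stop("filter thresholds must be non-negative", call. = FALSE)
  }
  structure(list(checks_only = checks_only,
                 exclude_years = exclude_years,
                 min_checks_per_cell = min_checks_per_cell,
                 min_years_per_site = min_years_per_site),
            class = "filter_rules")
}

#' Apply inclusion rules to a trial table
#'
#' Rules are applied in a fixed order — checks only, excluded years, minimum
#' checks per (site, year) cell (cells dropped whole), minimum years per site
#' (sites dropped whole) — and the whole operation is idempotent.
#'
#' @param trials Trial data frame.
#' @param rules A [filter_rules()] object.
#' @param quiet Suppress the per-rule record counts logged via [message()].
#' @return The filtered trial data frame (possibly empty).
#' @export
filter_trials <- function(trials, rules = filter_rules(), quiet = FALSE) {
  trials <- validate_trials(trials)
  if (!inherits(rules, "filter_rules")) stop("rules must come from filter_rules()",
                                             call. = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (rules$checks_only) {
    if (is.null(trials$is_check)) {
      stop("checks_only filtering requested but the data have no is_check column",
           call. = FALSE)
    }
    n0 <- nrow(trials)
    trials <- trials[trials$is_check %in% TRUE, , drop = FALSE]
    say("checks_only: dropped %d of %d records", n0 - nrow(trials), n0)
  }
  if (length(rules$exclude_years)) {
    n0 <- nrow(trials)
    trials <- trials[!trials$year %in% rules$exclude_years, , drop = FALSE]
    say("exclude_years: dropped %d of %d records", n0 - nrow(trials), n0)
  }
  if (rules$min_checks_per_cell > 0L && nrow(trials)) {
    cell <- paste(trials$site, trials$year, sep = "\r")
    nvar <- tapply(trials$variety, cell, function(v) length(unique(v)))
    keep <- names(nvar)[nvar >= rules$min_checks_per_cell]
    n0 <- nrow(trials)
    trials <- trials[cell %in% keep, , drop = FALSE]
    say("min_checks_per_cell: dropped %d records in %d small cells",
        n0 - nrow(trials), sum(nvar < rules$min_checks_per_cell))
  }
  if (rules$min_years_per_site > 0L && nrow(trials)) {
    nyr <- tapply(trials$year, trials$site, function(y) length(unique(y)))
    keep <- names(nyr)[nyr >= rules$min_years_per_site]
    n0 <- nrow(trials)
    trials <- trials[trials$site %in% keep, , drop = FALSE]
    say("min_years_per_site: dropped %d records at %d sparse sites",
        n0 - nrow(trials), sum(nyr < rules$min_years_per_site))
  }
  if (nrow(trials) == 0L) say("filtering removed every record")
  rownames(trials) <- NULL
  trials
}

# internal cell key shared by the z-scoring and permutation steps
cell_key <- function(trials) paste(trials$site, trials$year, sep = "\r")
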