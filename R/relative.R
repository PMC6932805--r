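#' Within-cell relative yields (z-scores)
#'
#' Expresses every record's yield as a z-score within its (site, year) cell:
#' the cell mean is subtracted and the result divided by the cell's sample
#' standard deviation (n - 1 denominator). Varieties are directly comparable
#' only within a cell, so these relative yields are the basis of the home
#' site definition.
#'
#' Cells with a single record or zero yield variance carry no ranking
#' information: their z-scores are set to 0 and flagged in the
#' `cell_degenerate` column.
#'
#' @param trials Trial data frame (see [read_trials()]).
#' @return The input with two extra columns, `rel_yield` (dimensionless) and
#'   `cell_degenerate` (logical).
#' @export
relative_yields <- function(trials) {
  trials <- validate_trials(trials)
  if (nrow(trials) == 0L) stop("cannot standardize an empty trial table",
                               call. = FALSE)
  cell <- cell_key(trials)
  mu <- ave(trials$yield, cell, FUN = mean)
  n <- ave(trials$yield, cell, FUN = length)
  sdv <- ave(trials$yield, cell, FUN = function(x) if (length(x) > 1L) sd(x) else 0)
  degen <- n < 2 | sdv == 0
  z <- ifelse(degen, 0, (trials$yield - mu) / ifelse(sdv == 0, 1, sdv))
  trials$rel_yield <- z
  trials$cell_degenerate <- degen
  trials
}

#' Assign each variety its home site
#'
#' A variety's home site is the site with its maximum mean relative yield
#' across years (each site-year it appears in contributes one z-score with
#' equal weight). Ties are broken toward the lexicographically smallest site
#' identifier so the assignment is deterministic and independent of record
#' order.
#'
#' @param rel Output of [relative_yields()].
#' @param min_cells Minimum number of site-year observations a variety needs
#'   to receive a home; varieties below it are excluded (and logged), not an
#'   error.
#' @return An object of class `home_map`: a list with
#'   \describe{
#'     \item[`home`]{data frame `variety`, `home_site`, `mean_rel_at_home`,
#'       `n_obs_at_home` (one row per assigned variety);}
#'     \item[`mean_rel`]{the variety x site mean relative-yield table in long
#'       form (`variety`, `site`, `mean_rel`, `n_obs`);}
#'     \item[`dropped`]{varieties excluded by `min_cells`.}
#'   }
#' @export
assign_home <- function(rel, min_cells = 1L) {
  if (!is.data.frame(rel) || is.null(rel$rel_yield)) {
    stop("rel must be the output of relative_yields()", call. = FALSE)
  }
  if (nrow(rel) == 0L) stop("cannot assign homes from an empty table", call. = FALSE)
  min_cells <- as.integer(min_cells)
  agg <- aggregate(rel$rel_yield,
                   by = list(variety = rel$variety, site = rel$site),
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  mean_rel <- data.frame(variety = agg$variety, site = agg$site,
                         mean_rel = agg$x[, "mean"],
                         n_obs = as.integer(agg$x[, "n"]),
                         stringsAsFactors = FALSE)
  mean_rel <- mean_rel[order(mean_rel$variety, mean_rel$site), , drop = FALSE]
  rownames(mean_rel) <- NULL

  tot <- tapply(mean_rel$n_obs, mean_rel$variety, sum)
  eligible <- names(tot)[tot >= min_cells]
  dropped <- setdiff(names(tot), eligible)
  if (length(dropped)) {
    message(sprintf("assign_home: %d variety(ies) below min_cells = %d excluded",
                    length(dropped), min_cells))
  }
  picks <- lapply(split(mean_rel[mean_rel$variety %in% eligible, , drop = FALSE],
                        mean_rel$variety[mean_rel$variety %in% eligible]),
                  function(d) {
                    best <- d$mean_rel == max(d$mean_rel)
                    # lexicographic tie-break: rows are already site-sorted
                    d[which(best)[1L], , drop = FALSE]
                  })
  home <- do.call(rbind, picks)
  home <- data.frame(variety = home$variety, home_site = home$site,
                     mean_rel_at_home = home$mean_rel,
                     n_obs_at_home = home$n_obs, stringsAsFactors = FALSE)
  home <- home[order(home$variety), , drop = FALSE]
  rownames(home) <- NULL
  structure(list(home = home, mean_rel = mean_rel, dropped = dropped,
                 min_cells = min_cells),
            class = "home_map")
}

#' @export
print.home_map <- function(x, ...) {
  cat(sprintf("home_map: %d varieties assigned across %d sites (%d excluded, min_cells = %d)\n",
              nrow(x$home), length(unique(x$home$home_site)),
              length(x$dropped), x$min_cells))
  print(head(x$home, 6L))
  if (nrow(x$home) > 6L) cat("...\n")
  invisible(x)
}

#' Home-site indicator for a trial table
#'
#' @param trials Trial data frame.
#' @param home A [assign_home()] `home_map`.
#' @return Integer 0/1 vector: is the record at its variety's home site?
#'   Records of varieties without a home get 0.
#' @export
is_home_indicator <- function(trials, home) {
  if (!inherits(home, "home_map")) stop("home must be a home_map", call. = FALSE)
  hs <- setNames(home$home$home_site, home$home$variety)
  as.integer(!is.na(hs[trials$variety]) & hs[trials$variety] == trials$site)
}

#' Export a home map as TSV
#'
#' @param home A `home_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_home_map <- function(home, path) {
  if (!inherits(home, "home_map")) stop("home must be a home_map", call. = FALSE)
  write.table(home$home, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
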