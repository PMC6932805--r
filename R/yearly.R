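#' Yearly home-field advantage by median quantile regression
#'
#' For every year separately, fits yield = genotype + site + is_home to that
#' year's records by least absolute deviations ([lad_fit()]) and reports the
#' `is_home` coefficient as the year's home-field advantage. The median
#' regression is robust to the skewed or heavy-tailed yield distributions
#' single seasons can show. Standard errors, when requested, come from case
#' resampling: records of the year are resampled with replacement `n_boot`
#' times and the SE is the standard deviation of the refitted coefficients.
#'
#' Years in which no record sits at a home site, or where the home indicator
#' is aliased with the genotype/site terms, cannot support an estimate; they
#' are skipped and logged, not an error.
#'
#' @inheritParams fit_hfa
#' @param n_boot Number of bootstrap refits per year; `0` disables the
#'   bootstrap and the SEs are reported as `NA`.
#' @param seed Integer seed for the bootstrap resampling; `NULL` leaves the
#'   RNG state alone.
#' @return Object of class `yearly_hfa`: data frame `year`, `estimate`
#'   (Mg/ha), `se`, `n_records`, `n_home`, with skipped years in
#'   `attr(, "skipped")`.
#' @export
yearly_hfa <- function(trials, home, n_boot = 200L, seed = NULL) {
  trials <- validate_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  n_boot <- as.integer(n_boot)
  years <- sort(unique(trials$year))
  rows <- vector("list", length(years))
  skipped <- character(0)
  for (i in seq_along(years)) {
    yr <- years[i]
    d <- trials[trials$year == yr, , drop = FALSE]
    d$is_home <- is_home_indicator(d, home)
    est <- yearly_lad_estimate(d)
    if (is.na(est)) {
      skipped <- c(skipped, as.character(yr))
      message("yearly_hfa: year ", yr, " skipped (home indicator not estimable)")
      next
    }
    se <- NA_real_
    if (n_boot > 0L) {
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        yearly_lad_estimate(d[idx, , drop = FALSE])
      }, numeric(1))
      se <- sd(boots, na.rm = TRUE)
    }
    rows[[i]] <- data.frame(year = yr, estimate = est, se = se,
                            n_records = nrow(d), n_home = sum(d$is_home))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(year = integer(0), estimate = numeric(0),
                                      se = numeric(0), n_records = integer(0),
                                      n_home = integer(0))
  rownames(out) <- NULL
  structure(out, skipped = skipped, class = c("yearly_hfa", "data.frame"))
}

# LAD is_home coefficient on one year's records; NA when not estimable
yearly_lad_estimate <- function(d) {
  if (sum(d$is_home) == 0L || length(unique(d$is_home)) < 2L) return(NA_real_)
  mm <- model.matrix(~ genotype + site,
                     data.frame(genotype = factor(d$variety),
                                site = factor(d$site)))
  x <- cbind(mm, is_home = d$is_home)
  if (nrow(x) <= qr(x)$rank) return(NA_real_)
  fit <- lad_fit(x, d$yield)
  est <- fit$coefficients["is_home"]
  if (is.na(est)) NA_real_ else unname(est)
}

#' Linear trend of a yearly series
#'
#' Ordinary least squares of a yearly quantity (e.g. the yearly home-field
#' advantage, or mean yield) on calendar year. The slope's p-value uses the
#' classical t distribution; no multiplicity correction is applied as the
#' trend is a single test.
#'
#' @param series Data frame whose first two columns are year and value (or
#'   columns named `year` and `value`).
#' @return List of class `trend_fit`: `slope` (response units per year),
#'   `intercept`, `adj_r2`, `p_slope`, `n`.
#' @export
trend_regression <- function(series) {
  if (!is.data.frame(series)) stop("series must be a data frame", call. = FALSE)
  nm <- names(series)
  d <- if (all(c("year", "value") %in% nm)) {
    data.frame(year = series$year, value = series$value)
  } else {
    data.frame(year = series[[1]], value = series[[2]])
  }
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3L) stop("trend regression needs at least 3 years", call. = FALSE)
  m <- lm(value ~ year, data = d)
  s <- summary(m)
  structure(list(slope = unname(coef(m)["year"]),
                 intercept = unname(coef(m)["(Intercept)"]),
                 adj_r2 = s$adj.r.squared,
                 p_slope = s$coefficients["year", "Pr(>|t|)"],
                 n = nrow(d)),
            class = "trend_fit")
}

#' Home advantage versus cross-environment stability
#'
#' Habitat specialization implies a trade-off: varieties with a large home
#' advantage should also be less stable elsewhere. Per variety this computes
#' (i) the home advantage as mean relative yield at the assigned home site
#' minus mean relative yield at all other sites, and (ii) yield variability
#' as the standard deviation of the variety's relative yields over all its
#' site-year cells, then regresses variability on home advantage by OLS.
#'
#' Varieties with fewer than two cells or with no away observations carry no
#' information and are excluded (and counted in `excluded`).
#'
#' @inheritParams fit_hfa
#' @return List: `slope`, `intercept`, `r2`, `p_slope`, `n_varieties`,
#'   `excluded`, and the per-variety table `data` (`variety`, `home_adv`,
#'   `variability`).
#' @export
stability_regression <- function(trials, home) {
  rel <- relative_yields(trials)
  hs <- setNames(home$home$home_site, home$home$variety)
  per <- lapply(split(rel, rel$variety), function(d) {
    v <- d$variety[1L]
    if (is.na(hs[v]) || nrow(d) < 2L) return(NULL)
    at_home <- d$site == hs[v]
    if (!any(at_home) || all(at_home)) return(NULL)
    data.frame(variety = v,
               home_adv = mean(d$rel_yield[at_home]) - mean(d$rel_yield[!at_home]),
               variability = sd(d$rel_yield))
  })
  keep <- !vapply(per, is.null, logical(1))
  tab <- do.call(rbind, per[keep])
  n_excl <- sum(!keep)
  if (n_excl) message("stability_regression: ", n_excl,
                      " variety(ies) without usable home/away contrast excluded")
  if (is.null(tab) || nrow(tab) < 3L) {
    stop("stability regression needs >= 3 varieties with home and away records",
         call. = FALSE)
  }
  if (sd(tab$home_adv) == 0 || sd(tab$variability) == 0) {
    stop("degenerate input: home advantages or variabilities have zero variance",
         call. = FALSE)
  }
  m <- lm(variability ~ home_adv, data = tab)
  s <- summary(m)
  rownames(tab) <- NULL
  list(slope = unname(coef(m)["home_adv"]),
       intercept = unname(coef(m)["(Intercept)"]),
       r2 = s$r.squared,
       p_slope = s$coefficients["home_adv", "Pr(>|t|)"],
       n_varieties = nrow(tab), excluded = n_excl, data = tab)
}
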