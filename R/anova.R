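#' Type-II variance partition of trial yields
#'
#' Partitions yield variation among genotype, site, year and the site-year
#' interaction (optionally plus the home indicator) with Type-II sums of
#' squares: every term is adjusted for all terms that do not contain it, so
#' main effects are adjusted for the other main effects and the interaction
#' is adjusted for all of them. Computation is delegated to
#' [car::Anova()] (type 2), which falls back to explicit model comparisons
#' when empty site-year cells alias interaction coefficients — the normal
#' situation in unbalanced trial networks.
#'
#' In unbalanced data Type-II sums of squares need not add up to the total
#' sum of squares, so the reported `share` column is normalized over the sum
#' of all term SS plus the residual SS; raw SS are kept alongside.
#'
#' @inheritParams fit_hfa
#' @param include_home Add the home indicator as a term of the partition?
#' @return Object of class `variance_partition`: a data frame with columns
#'   `term`, `sum_sq`, `df`, `share`, `p_value` (residual row included,
#'   `p_value` `NA` there). Non-estimable terms are reported with zero df
#'   and flagged by an `estimable` column.
#' @export
variance_partition <- function(trials, home = NULL, include_home = FALSE) {
  trials <- validate_trials(trials)
  d <- data.frame(yield = trials$yield,
                  genotype = factor(trials$variety),
                  site = factor(trials$site),
                  year = factor(trials$year))
  for (f in c("genotype", "site", "year")) {
    if (nlevels(d[[f]]) < 2L) {
      stop(sprintf("factor '%s' needs at least 2 observed levels", f),
           call. = FALSE)
    }
  }
  if (include_home) {
    if (is.null(home)) stop("include_home = TRUE requires a home map", call. = FALSE)
    d$is_home <- is_home_indicator(trials, home)
    form <- yield ~ genotype + site + year + site:year + is_home
  } else {
    form <- yield ~ genotype + site + year + site:year
  }
  m <- lm(form, data = d)
  a <- suppressMessages(car::Anova(m, type = 2, singular.ok = TRUE))
  tab <- as.data.frame(a)
  terms <- rownames(tab)
  resid_row <- terms == "Residuals"
  out <- data.frame(term = terms,
                    sum_sq = tab[["Sum Sq"]],
                    df = tab[["Df"]],
                    p_value = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]] else NA_real_,
                    stringsAsFactors = FALSE)
  out$estimable <- out$df > 0 | resid_row
  if (any(!out$estimable)) {
    message("variance_partition: non-estimable term(s): ",
            paste(out$term[!out$estimable], collapse = ", "))
    out$sum_sq[!out$estimable] <- 0
  }
  out$share <- out$sum_sq / sum(out$sum_sq)
  out$p_value[resid_row] <- NA_real_
  rownames(out) <- NULL
  structure(out[, c("term", "sum_sq", "df", "share", "p_value", "estimable")],
            class = c("variance_partition", "data.frame"))
}
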