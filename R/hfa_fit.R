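#' Least-squares engine shared by the yield models
#'
#' Thin wrapper around [lm()] that returns the quantities the rest of the
#' pipeline needs in one flat structure. Factors use treatment coding with
#' the lexicographically first level as reference; rank-deficient designs are
#' handled by pivoting (aliased coefficients come back `NA`). The Gaussian
#' log-likelihood is evaluated at the MLE variance and the information
#' criteria count the variance parameter, i.e. `aic = -2*loglik + 2*(rank+1)`
#' and `bic = -2*loglik + (rank+1)*log(n)`.
#'
#' @param formula Model formula.
#' @param data Data frame; character columns entering the formula are
#'   converted to factors with sorted levels.
#' @return List of class `hfa_fit`: `coefficients`, `se`, `loglik`, `aic`,
#'   `bic`, `n`, `rank`, `residuals`, `rss`, and the underlying `model`.
#' @export
fit_linear_model <- function(formula, data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("model data must be a non-empty data frame", call. = FALSE)
  }
  data <- data.frame(lapply(data, function(col) {
    if (is.character(col)) factor(col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  m <- lm(formula, data = data)
  ll <- as.numeric(logLik(m))
  k <- m$rank + 1L
  smry <- summary(m)$coefficients
  se <- setNames(rep(NA_real_, length(coef(m))), names(coef(m)))
  se[rownames(smry)] <- smry[, "Std. Error"]
  structure(list(coefficients = coef(m), se = se, loglik = ll,
                 aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(nobs(m)),
                 n = nobs(m), rank = m$rank,
                 residuals = as.numeric(m$residuals),
                 rss = sum(m$residuals^2), model = m),
            class = "hfa_fit")
}

#' @export
print.hfa_fit <- function(x, ...) {
  cat(sprintf("hfa_fit: n = %d, rank = %d, AIC = %.1f, BIC = %.1f\n",
              x$n, x$rank, x$aic, x$bic))
  if (!is.null(x$hfa)) {
    cat(sprintf("  home-field advantage: %.3f (model SE %.3f) Mg/ha\n",
                x$hfa, x$hfa_se))
  }
  invisible(x)
}

#' Fit the home-field advantage yield model
#'
#' Fits yield = genotype + site + year + site:year (+ is_home) by least
#' squares, with `year` as a factor. The coefficient of the `is_home`
#' indicator is the overall home-field advantage in Mg/ha: the yield a
#' variety gains at its home site beyond its genetic potential and the
#' site/year/site-year effects. Variety-site, variety-year and three-way
#' interactions are deliberately absent — check varieties are too thinly
#' replicated across years for them to be estimable.
#'
#' @param trials Trial data frame.
#' @param home A [assign_home()] `home_map`.
#' @param include_home Include the home indicator (the full model)? With
#'   `FALSE` the control model is fitted instead.
#' @return An `hfa_fit` (see [fit_linear_model()]); when `include_home` is
#'   `TRUE` it carries `hfa` and `hfa_se`, the `is_home` coefficient and its
#'   model standard error.
#' @export
fit_hfa <- function(trials, home, include_home = TRUE) {
  trials <- validate_trials(trials)
  d <- data.frame(yield = trials$yield,
                  genotype = factor(trials$variety),
                  site = factor(trials$site),
                  year = factor(trials$year),
                  is_home = is_home_indicator(trials, home))
  if (include_home && sum(d$is_home) == 0L) {
    stop("degenerate design: no record is at its variety's home site",
         call. = FALSE)
  }
  form <- if (include_home) {
    yield ~ genotype + site + year + site:year + is_home
  } else {
    yield ~ genotype + site + year + site:year
  }
  fit <- fit_linear_model(form, d)
  if (include_home) {
    if (is.na(fit$coefficients["is_home"])) {
      stop("degenerate design: the home indicator is aliased with the factor terms",
           call. = FALSE)
    }
    fit$hfa <- unname(fit$coefficients["is_home"])
    fit$hfa_se <- unname(fit$se["is_home"])
  }
  fit$include_home <- include_home
  fit
}

#' Case-bootstrap standard error of the overall home-field advantage
#'
#' Resamples records with replacement within each year (preserving the
#' yearly structure of the unbalanced design), refits the full model, and
#' returns the standard deviation of the `is_home` coefficient across
#' refits. Refits in which the home indicator becomes aliased or constant
#' contribute nothing and are counted in `n_failed`. This SE, like the model
#' SE, is conditional on the home assignment; the selection step itself is
#' benchmarked by the permutation null, not by a standard error.
#'
#' @inheritParams fit_hfa
#' @param n_boot Number of bootstrap refits.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List: `se`, `estimates` (per successful refit), `n_failed`.
#' @export
hfa_case_bootstrap <- function(trials, home, n_boot = 200L, seed = NULL) {
  trials <- validate_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  idx_by_year <- split(seq_len(nrow(trials)), trials$year)
  ests <- vapply(seq_len(as.integer(n_boot)), function(b) {
    idx <- unlist(lapply(idx_by_year, function(ix) {
      ix[sample.int(length(ix), replace = TRUE)]
    }), use.names = FALSE)
    d <- trials[idx, , drop = FALSE]
    d$variety <- paste0(d$variety, "")  # drop any factor memory
    tryCatch(fit_hfa_resample(d, home), error = function(e) NA_real_)
  }, numeric(1))
  ok <- ests[!is.na(ests)]
  list(se = if (length(ok) > 1L) sd(ok) else NA_real_,
       estimates = ok, n_failed = sum(is.na(ests)))
}

# resampled rows break the (variety, site, year) uniqueness invariant on
# purpose, so the bootstrap refit bypasses validate_trials
fit_hfa_resample <- function(d, home) {
  dd <- data.frame(yield = d$yield, genotype = factor(d$variety),
                   site = factor(d$site), year = factor(d$year),
                   is_home = is_home_indicator(d, home))
  if (sum(dd$is_home) == 0L || length(unique(dd$is_home)) < 2L) {
    stop("no home contrast in resample", call. = FALSE)
  }
  form <- if (nlevels(dd$year) > 1L) {
    yield ~ genotype + site + year + site:year + is_home
  } else {
    yield ~ genotype + site + is_home
  }
  m <- lm(form, data = dd)
  est <- coef(m)["is_home"]
  if (is.na(est)) stop("home indicator aliased in resample", call. = FALSE)
  unname(est)
}

#' Compare the full and control yield models
#'
#' Information-criterion comparison of the model with the home indicator
#' against the control without it, on the identical response. Deltas are
#' control minus full, so positive values favor keeping the home term.
#'
#' @param full `hfa_fit` with the home indicator.
#' @param control `hfa_fit` without it.
#' @return List: `delta_aic`, `delta_bic`, `aic_full`, `aic_control`,
#'   `bic_full`, `bic_control`.
#' @export
compare_models <- function(full, control) {
  stopifnot(inherits(full, "hfa_fit"), inherits(control, "hfa_fit"))
  if (full$n != control$n) {
    stop("models were fit to different numbers of records", call. = FALSE)
  }
  if (is.null(full$hfa) || is.na(full$coefficients["is_home"])) {
    stop("the full model does not carry an estimated home term; ",
         "refusing a comparison that would only measure the penalty",
         call. = FALSE)
  }
  list(delta_aic = control$aic - full$aic,
       delta_bic = control$bic - full$bic,
       aic_full = full$aic, aic_control = control$aic,
       bic_full = full$bic, bic_control = control$bic)
}

#' Share of residual variation explained by the home term
#'
#' How much of the control model's residual sum of squares the home
#' indicator absorbs, and the same numerator expressed against the total
#' (corrected) sum of squares of yield.
#'
#' @inheritParams fit_hfa
#' @return List: `share_residual`, `share_total`, `rss_control`, `rss_full`,
#'   `degenerate` (`TRUE` when the control model leaves no residual to
#'   explain, in which case both shares are defined as 0).
#' @export
home_share_of_residual <- function(trials, home) {
  full <- fit_hfa(trials, home, include_home = TRUE)
  control <- fit_hfa(trials, home, include_home = FALSE)
  tss <- sum((trials$yield - mean(trials$yield))^2)
  if (control$rss <= 1e-12 * max(1, tss)) {
    return(list(share_residual = 0, share_total = 0,
                rss_control = control$rss, rss_full = full$rss,
                degenerate = TRUE))
  }
  num <- control$rss - full$rss
  list(share_residual = num / control$rss,
       share_total = num / tss,
       rss_control = control$rss, rss_full = full$rss,
       degenerate = FALSE)
}
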