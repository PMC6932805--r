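#' Shuffle yields among varieties within each site-year cell
#'
#' The strategy-neutral counterfactual: within every (site, year) cell the
#' observed yields are reassigned to that cell's varieties by a uniform
#' random permutation. Cell-level structure (site, year, site-year effects,
#' the yield multiset of each cell) is preserved exactly; genotype-specific
#' advantages are destroyed. All non-yield fields are untouched.
#'
#' @param trials Trial data frame.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return The trial data frame with permuted `yield` values.
#' @export
permute_within_cells <- function(trials, seed = NULL) {
  trials <- validate_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  cell <- cell_key(trials)
  idx <- seq_len(nrow(trials))
  for (rows in unname(split(idx, cell))) {
    if (length(rows) > 1L) {
      trials$yield[rows] <- trials$yield[rows][sample.int(length(rows))]
    }
  }
  trials
}

#' Permutation null distribution of the yearly home-field advantage
#'
#' Repeats the full selection-plus-estimation procedure on permuted data:
#' each replicate shuffles yields within site-year cells
#' ([permute_within_cells()]), re-assigns home sites from the permuted data
#' ([assign_home()] with the same `min_cells` and tie-break as the observed
#' analysis), and re-estimates the yearly advantage ([yearly_hfa()]).
#' Because home sites are re-selected by argmax inside every replicate, the
#' null distribution carries the same selection (Beavis-type) bias as the
#' observed estimate — which is exactly what makes it the right reference.
#'
#' Replicates are driven by per-replicate seeds drawn up-front from the
#' master seed, so the distribution is reproducible and independent of
#' execution order.
#'
#' @inheritParams fit_hfa
#' @param n_perm Number of permutation replicates (the reference analysis
#'   uses 999).
#' @param n_boot Bootstrap refits inside each replicate's [yearly_hfa()];
#'   default 0 (the envelopes need only the point estimates).
#' @param seed Master integer seed.
#' @param min_cells Passed to [assign_home()].
#' @return Object of class `hfa_null`: list with `draws` (matrix
#'   `n_perm` x years; an `NA` entry marks a replicate-year that could not
#'   be estimated), `years`, `n_perm`, `seed`, and `skipped` (count of `NA`
#'   entries per year).
#' @export
null_distribution <- function(trials, n_perm = 999L, n_boot = 0L, seed = 1L,
                              min_cells = 1L) {
  trials <- validate_trials(trials)
  n_perm <- as.integer(n_perm)
  if (n_perm < 0L) stop("n_perm must be >= 0", call. = FALSE)
  years <- sort(unique(trials$year))
  draws <- matrix(NA_real_, nrow = n_perm, ncol = length(years),
                  dimnames = list(NULL, as.character(years)))
  if (n_perm > 0L) {
    set.seed(as.integer(seed))
    rep_seeds <- sample.int(.Machine$integer.max, n_perm)
    for (r in seq_len(n_perm)) {
      set.seed(rep_seeds[r])
      perm <- permute_within_cells(trials)
      hm <- suppressMessages(assign_home(relative_yields(perm), min_cells))
      yh <- suppressMessages(yearly_hfa(perm, hm, n_boot = n_boot))
      draws[r, as.character(yh$year)] <- yh$estimate
    }
  }
  skipped <- colSums(is.na(draws))
  if (n_perm > 0L && any(skipped > 0)) {
    message("null_distribution: some replicate-years were not estimable: ",
            paste(sprintf("%s (%d)", names(skipped)[skipped > 0],
                          skipped[skipped > 0]), collapse = ", "))
  }
  structure(list(draws = draws, years = years, n_perm = n_perm,
                 seed = as.integer(seed), skipped = skipped),
            class = "hfa_null")
}

#' @export
print.hfa_null <- function(x, ...) {
  cat(sprintf("hfa_null: %d permutation replicates over %d years (seed %d)\n",
              x$n_perm, length(x$years), x$seed))
  invisible(x)
}

#' Summarize a permutation null distribution
#'
#' Per-year sample quantiles (type 7, linear interpolation) of the null
#' draws, and — when observed estimates are supplied — the per-year
#' empirical tail proportion, the fraction of null values less than or equal
#' to the observed value.
#'
#' @param nd An `hfa_null` from [null_distribution()].
#' @param probs Quantile probabilities; the default reproduces a median plus
#'   50% and 90% envelopes.
#' @param observed Optional [yearly_hfa()] result (or data frame with `year`
#'   and `estimate`).
#' @return List with `quantiles` (long data frame `year`, `prob`,
#'   `quantile`) and, if `observed` was given, `tails` (data frame `year`,
#'   `observed`, `tail_prop`, `n_null`).
#' @export
null_summary <- function(nd, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                         observed = NULL) {
  if (!inherits(nd, "hfa_null")) stop("nd must be an hfa_null", call. = FALSE)
  if (nd$n_perm == 0L || all(is.na(nd$draws))) {
    stop("cannot summarize an empty null distribution", call. = FALSE)
  }
  qs <- lapply(seq_along(nd$years), function(j) {
    v <- nd$draws[, j]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(year = nd$years[j], prob = probs,
               quantile = unname(quantile(v, probs, type = 7)))
  })
  quantiles <- do.call(rbind, qs[!vapply(qs, is.null, logical(1))])
  rownames(quantiles) <- NULL
  out <- list(quantiles = quantiles)
  if (!is.null(observed)) {
    obs <- data.frame(year = observed$year, observed = observed$estimate)
    tails <- lapply(seq_len(nrow(obs)), function(i) {
      j <- match(as.character(obs$year[i]), colnames(nd$draws))
      if (is.na(j)) return(NULL)
      v <- nd$draws[, j]; v <- v[!is.na(v)]
      if (!length(v)) return(NULL)
      data.frame(year = obs$year[i], observed = obs$observed[i],
                 tail_prop = mean(v <= obs$observed[i]), n_null = length(v))
    })
    out$tails <- do.call(rbind, tails[!vapply(tails, is.null, logical(1))])
    rownames(out$tails) <- NULL
  }
  out
}
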