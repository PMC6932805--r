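#' Parameters of the synthetic trial generator
#'
#' Defines the generative truth of [generate_trials()]: an additive yield
#' model with independent Gaussian effects and an optional planted home
#' premium,
#' \deqn{y = \mu + g_i + s_j + t_k + (st)_{jk} + (gs)_{ij}
#'       + \delta\,1[j = home(i)] + \epsilon}
#' on an unbalanced check-variety design.
#'
#' The defaults mirror the scale and structure of a state-wide maize
#' variety-trial network: 14 sites observed over 18 years, a pool of 230
#' check varieties each serving two consecutive campaign years at a small
#' group of sites (about three records per variety, the sparsity typical of
#' check entries; overlapping years are what link year effects to the data),
#' rotating 3-variety check panels per site-year, a grand mean of
#' 13.3 Mg/ha, effect SDs whose variance
#' fractions match the partition typical of such networks (site dominating,
#' then site-year, genotype, year), and a home premium of 1 Mg/ha. A
#' Student-t residual option (`resid_df < Inf`, scaled to `sigma_e`) is
#' available to emulate the heavy-tailed seasons that motivate median
#' regression.
#'
#' @param mu Grand mean yield (Mg/ha).
#' @param sigma_g,sigma_s,sigma_y,sigma_sy,sigma_gs,sigma_e SDs (Mg/ha) of
#'   the genotype, site, year, site-year, genotype-site and residual
#'   effects.
#' @param delta Planted home-site premium (Mg/ha).
#' @param n_sites,n_years,n_varieties Design dimensions.
#' @param varieties_per_cell Check panel size per (site, year) cell.
#' @param years_per_variety Consecutive years each variety stays in the
#'   network.
#' @param resid_df Degrees of freedom of the residual distribution;
#'   `Inf` = Gaussian.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   parameter set.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(mu = 13.3,
                         sigma_g = 0.84, sigma_s = 1.71, sigma_y = 0.35,
                         sigma_sy = 1.52, sigma_gs = 0, sigma_e = 0.90,
                         delta = 1.0,
                         n_sites = 14L, n_years = 18L, n_varieties = 230L,
                         varieties_per_cell = 3L, years_per_variety = 2L,
                         resid_df = Inf, seed = 1L) {
  p <- list(mu = mu, sigma_g = sigma_g, sigma_s = sigma_s, sigma_y = sigma_y,
            sigma_sy = sigma_sy, sigma_gs = sigma_gs, sigma_e = sigma_e,
            delta = delta, n_sites = as.integer(n_sites),
            n_years = as.integer(n_years),
            n_varieties = as.integer(n_varieties),
            varieties_per_cell = as.integer(varieties_per_cell),
            years_per_variety = as.integer(years_per_variety),
            resid_df = resid_df, seed = as.integer(seed))
  sds <- unlist(p[c("sigma_g", "sigma_s", "sigma_y", "sigma_sy", "sigma_gs",
                    "sigma_e")])
  if (any(sds < 0)) stop("effect SDs must be >= 0", call. = FALSE)
  ints <- unlist(p[c("n_sites", "n_years", "n_varieties", "varieties_per_cell",
                     "years_per_variety")])
  if (any(ints < 1L)) stop("design dimensions must be >= 1", call. = FALSE)
  if (p$varieties_per_cell > p$n_varieties) {
    stop("infeasible design: check panel larger than the variety pool",
         call. = FALSE)
  }
  if (p$years_per_variety > p$n_years) {
    stop("infeasible design: years_per_variety exceeds n_years", call. = FALSE)
  }
  if (!is.infinite(p$resid_df) && p$resid_df <= 2) {
    stop("resid_df must exceed 2 (finite residual variance)", call. = FALSE)
  }
  structure(p, class = "synth_params")
}

#' Generate a synthetic multi-environment trial dataset
#'
#' Builds the unbalanced design — each variety enters for
#' `years_per_variety` consecutive years, and every (site, year) cell holds
#' a rotating panel of `varieties_per_cell` of that year's active
#' varieties — then draws all effects i.i.d. normal with the SDs in
#' `params`, picks each variety's true home uniformly among the sites where
#' it is observed, and adds `delta` to its records there. All records are
#' flagged as checks. The same seed reproduces the dataset exactly.
#'
#' @param params A [synth_params()] object.
#' @return List with `trials` (canonical trial data frame, columns as
#'   [read_trials()] plus `is_check = TRUE`) and `truth` (class
#'   `synth_truth`: per-level effect vectors, the true `home` per variety,
#'   and the parameters).
#' @export
generate_trials <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) {
    stop("params must come from synth_params()", call. = FALSE)
  }
  p <- params
  set.seed(p$seed)
  sites <- sprintf("S%02d", seq_len(p$n_sites))
  years <- 2000L + seq_len(p$n_years) - 1L
  varieties <- sprintf("V%03d", seq_len(p$n_varieties))

  n_starts <- p$n_years - p$years_per_variety + 1L
  start <- rep(seq_len(n_starts), length.out = p$n_varieties)
  start <- sort(start)  # consecutive entry cohorts
  active <- lapply(seq_len(p$n_years), function(t) {
    which(start <= t & t <= start + p$years_per_variety - 1L)
  })
  n_active <- lengths(active)
  if (any(n_active < p$varieties_per_cell)) {
    stop("infeasible design: a year has fewer active varieties than the panel size",
         call. = FALSE)
  }

  # Panel structure: each year's active pool is split into rotating panels of
  # varieties_per_cell checks, and every site carries exactly one panel, so a
  # check is replicated across a group of sites within its year(s) — the way
  # control varieties anchor comparisons in a regional trial network — while
  # every cell holds exactly varieties_per_cell distinct checks.
  if (any(n_active > p$n_sites * p$varieties_per_cell)) {
    stop("infeasible design: more active varieties in a year than cell slots",
         call. = FALSE)
  }
  rows <- vector("list", p$n_years)
  for (t in seq_len(p$n_years)) {
    act <- active[[t]]
    n_panels <- min(ceiling(length(act) / p$varieties_per_cell), p$n_sites)
    panel_of <- function(pnl) act[((pnl - 1L) * p$varieties_per_cell +
                                     seq_len(p$varieties_per_cell) - 1L) %%
                                    length(act) + 1L]
    site_panel <- (seq_len(p$n_sites) - 1L + (t - 1L)) %% n_panels + 1L
    rows[[t]] <- do.call(rbind, lapply(seq_len(p$n_sites), function(j) {
      data.frame(vi = panel_of(site_panel[j]), si = j, ti = t)
    }))
  }
  d <- do.call(rbind, rows)
  d <- d[!duplicated(d[c("vi", "si", "ti")]), , drop = FALSE]

  g <- setNames(rnorm(p$n_varieties, 0, p$sigma_g), varieties)
  s <- setNames(rnorm(p$n_sites, 0, p$sigma_s), sites)
  yr <- setNames(rnorm(p$n_years, 0, p$sigma_y), as.character(years))
  sy <- matrix(rnorm(p$n_sites * p$n_years, 0, p$sigma_sy),
               p$n_sites, p$n_years, dimnames = list(sites, as.character(years)))
  gs <- matrix(if (p$sigma_gs > 0) rnorm(p$n_varieties * p$n_sites, 0, p$sigma_gs)
               else 0,
               p$n_varieties, p$n_sites, dimnames = list(varieties, sites))

  obs_sites <- lapply(split(d$si, d$vi), unique)
  home_idx <- vapply(obs_sites, function(ss) {
    if (length(ss) == 1L) ss else ss[sample.int(length(ss), 1L)]
  }, integer(1))
  home <- setNames(sites[home_idx], varieties[as.integer(names(obs_sites))])

  eps <- if (is.infinite(p$resid_df)) {
    rnorm(nrow(d), 0, p$sigma_e)
  } else {
    rt(nrow(d), df = p$resid_df) * p$sigma_e / sqrt(p$resid_df / (p$resid_df - 2))
  }
  at_home <- sites[d$si] == home[varieties[d$vi]]
  yield <- p$mu + g[d$vi] + s[d$si] + yr[d$ti] + sy[cbind(d$si, d$ti)] +
    gs[cbind(d$vi, d$si)] + p$delta * at_home + eps

  trials <- data.frame(variety = varieties[d$vi], site = sites[d$si],
                       year = years[d$ti], yield = unname(yield),
                       is_check = TRUE, stringsAsFactors = FALSE)
  trials <- trials[order(trials$year, trials$site, trials$variety), , drop = FALSE]
  rownames(trials) <- NULL
  truth <- structure(list(genotype = g, site = s, year = yr, site_year = sy,
                          genotype_site = gs, home = home, params = p),
                     class = "synth_truth")
  list(trials = validate_trials_synth(trials), truth = truth)
}

# negative yields can only arise under extreme parameter choices; they are a
# parameterization error, not data to be clamped
validate_trials_synth <- function(trials) {
  if (any(trials$yield < 0)) {
    stop("generator produced negative yields; reduce the effect SDs or raise mu",
         call. = FALSE)
  }
  validate_trials(trials)
}

#' Write generator truth as JSON
#'
#' @param truth A `synth_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "synth_truth")) stop("not a synth_truth", call. = FALSE)
  out <- list(params = unclass(truth$params),
              home = as.list(truth$home),
              genotype = as.list(truth$genotype),
              site = as.list(truth$site),
              year = as.list(truth$year))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
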