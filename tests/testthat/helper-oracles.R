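# Independent oracles and small fixtures used across the suite. Every oracle
# here is deliberately implemented by a different route than the package code
# it checks (explicit loops, enumeration, closed forms).

# hand-built toy trial table: 3 cells, unbalanced
toy_trials <- function() {
  data.frame(
    variety = c("A", "B", "C", "A", "B", "C", "D", "A", "B"),
    site = c("N1", "N1", "N1", "S1", "S1", "S1", "S1", "N1", "N1"),
    year = c(2001L, 2001L, 2001L, 2001L, 2001L, 2001L, 2001L, 2002L, 2002L),
    yield = c(10, 12, 14, 9, 9.5, 11, 10.5, 8, 9),
    is_check = TRUE,
    stringsAsFactors = FALSE
  )
}

# small generator settings that keep every year's LAD model estimable
small_params <- function(seed, delta = 0, n_sites = 6L, n_years = 3L,
                         n_varieties = 18L, vpc = 3L, ypv = 1L,
                         sigma_g = 0.6, sigma_s = 1.2, sigma_y = 0.3,
                         sigma_sy = 1.0, sigma_gs = 0, sigma_e = 0.7,
                         mu = 13.3, resid_df = Inf) {
  synth_params(mu = mu, sigma_g = sigma_g, sigma_s = sigma_s,
               sigma_y = sigma_y, sigma_sy = sigma_sy, sigma_gs = sigma_gs,
               sigma_e = sigma_e, delta = delta, n_sites = n_sites,
               n_years = n_years, n_varieties = n_varieties,
               varieties_per_cell = vpc, years_per_variety = ypv,
               resid_df = resid_df, seed = seed)
}

# home_map carrying the generator's true homes (for recovery tests)
truth_home_map <- function(truth) {
  home <- truth$home
  structure(list(home = data.frame(variety = names(home),
                                   home_site = unname(home),
                                   mean_rel_at_home = NA_real_,
                                   n_obs_at_home = NA_integer_,
                                   stringsAsFactors = FALSE),
                 mean_rel = NULL, dropped = character(0), min_cells = 1L),
            class = "home_map")
}

# two-pass mean/SD, written as explicit loops
moments_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(mean = m, sd = if (n > 1) sqrt(ss / (n - 1)) else 0)
}

# least squares through the SVD pseudoinverse (normal-equations-free)
pinv_lsq_oracle <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * max(s$d)
  coef <- s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
  list(coef = drop(coef), fitted = drop(X %*% coef))
}

# exact LAD optimum by enumerating all p-point interpolating vertices
lad_enum_oracle <- function(X, y) {
  n <- nrow(X); p <- ncol(X); best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-9) next
    b <- solve(Xi, y[idx])
    ob <- sum(abs(y - drop(X %*% b)))
    if (ob < best) best <- ob
  }
  best
}

# Type-II sums of squares by explicit nested model comparisons: every term
# is adjusted for all terms it is not marginal to (site and year are marginal
# to site:year, genotype and is_home are not)
type2_nested_oracle <- function(d, include_home = FALSE) {
  rss <- function(f) sum(stats::resid(stats::lm(f, data = d))^2)
  if (!include_home) {
    c(
      genotype = rss(yield ~ site + year + site:year) -
        rss(yield ~ genotype + site + year + site:year),
      site = rss(yield ~ genotype + year) - rss(yield ~ genotype + site + year),
      year = rss(yield ~ genotype + site) - rss(yield ~ genotype + site + year),
      `site:year` = rss(yield ~ genotype + site + year) -
        rss(yield ~ genotype + site + year + site:year)
    )
  } else {
    c(
      genotype = rss(yield ~ site + year + site:year + is_home) -
        rss(yield ~ genotype + site + year + site:year + is_home),
      site = rss(yield ~ genotype + year + is_home) -
        rss(yield ~ genotype + site + year + is_home),
      year = rss(yield ~ genotype + site + is_home) -
        rss(yield ~ genotype + site + year + is_home),
      `site:year` = rss(yield ~ genotype + site + year + is_home) -
        rss(yield ~ genotype + site + year + is_home + site:year),
      is_home = rss(yield ~ genotype + site + year + site:year) -
        rss(yield ~ genotype + site + year + site:year + is_home)
    )
  }
}

# sort-and-interpolate type-7 quantile
quantile7_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# closed-form simple linear regression
simple_reg_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}
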