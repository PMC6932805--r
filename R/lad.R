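#' Least absolute deviations (median quantile regression) fit
#'
#' Minimizes the sum of absolute residuals \eqn{\sum_i |y_i - x_i'b|}, i.e.
#' quantile regression at \eqn{\tau = 0.5}. The solver runs a smoothed
#' iteratively-reweighted least-squares continuation (an MM scheme on
#' \eqn{\sum_i \sqrt{r_i^2 + \epsilon^2}} with \eqn{\epsilon} driven toward
#' zero) and then polishes the solution onto an exact vertex: an LAD optimum
#' always interpolates `ncol(x)` affinely independent observations, so the
#' smallest-residual rows are solved exactly and the result is certified
#' against the subgradient optimality condition. When the certificate holds
#' the returned objective is the exact optimum; minimizers need not be unique
#' (the vertex reached is reported).
#'
#' @param x Numeric design matrix. Rank-deficient columns are dropped by QR
#'   pivoting and reported as `NA` coefficients.
#' @param y Numeric response, `length(y) == nrow(x)`.
#' @param eps_final Smallest smoothing scale of the continuation phase.
#' @return List with `coefficients` (length `ncol(x)`, `NA` for aliased
#'   columns), `residuals`, `objective` (sum of absolute residuals),
#'   `certified` (logical: vertex optimality certificate), `rank`, and
#'   `iterations`.
#' @examples
#' x <- cbind(1, 1:6)
#' lad_fit(x, c(1, 2, 3, 4, 5, 60))$coefficients  # slope 1, robust to outlier
#' @export
lad_fit <- function(x, y, eps_final = 1e-8) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("response length mismatch", call. = FALSE)
  if (nrow(x) == 0L) stop("empty design", call. = FALSE)
  qx <- qr(x)
  rank <- qx$rank
  if (rank == 0L) stop("design has no estimable parameter", call. = FALSE)
  keep <- qx$pivot[seq_len(rank)]
  if (length(y) <= rank) {
    # saturated or under-determined: interpolate the estimable subspace
    b <- qr.coef(qr(x[, keep, drop = FALSE]), y)
    r <- y - drop(x[, keep, drop = FALSE] %*% b)
    out_coef <- rep(NA_real_, ncol(x)); out_coef[keep] <- b
    return(list(coefficients = named_like(out_coef, x),
                residuals = r, objective = sum(abs(r)),
                certified = FALSE, rank = rank, iterations = 0L))
  }
  xk <- x[, keep, drop = FALSE]

  f0 <- .lm.fit(xk, y)
  b <- numeric(rank); b[f0$pivot] <- f0$coefficients
  r <- y - drop(xk %*% b)
  it <- 0L
  mm <- function(b, r, eps_stop, max_it) {
    s <- max(mad(r), 1e-4 * max(1, mean(abs(y))))
    eps_stop <- min(eps_stop, s * 0.1)
    for (eps in s * 10^seq(-1, floor(log10(eps_stop / s)), by = -1)) {
      obj <- sum(sqrt(r^2 + eps^2))
      for (i in seq_len(max_it)) {
        sw <- 1 / sqrt(sqrt(r^2 + eps^2))
        f <- .lm.fit(xk * sw, y * sw)
        b <- numeric(rank); b[f$pivot] <- f$coefficients
        r <- y - drop(xk %*% b)
        it <<- it + 1L
        objn <- sum(sqrt(r^2 + eps^2))
        if (obj - objn < 1e-11 * (1 + objn)) break
        obj <- objn
      }
    }
    list(b = b, r = r)
  }
  st <- mm(b, r, 1e-5, 12L)
  best <- lad_polish(xk, y, st$b, st$r)
  if (!best$certified) {
    st <- mm(best$coef, best$residuals, eps_final, 40L)
    alt <- lad_polish(xk, y, st$b, st$r)
    if (alt$objective <= best$objective) best <- alt
  }
  out_coef <- rep(NA_real_, ncol(x)); out_coef[keep] <- best$coef
  list(coefficients = named_like(out_coef, x), residuals = best$residuals,
       objective = best$objective, certified = best$certified,
       rank = rank, iterations = it)
}

named_like <- function(b, x) {
  if (!is.null(colnames(x))) names(b) <- colnames(x)
  b
}

# Exact-vertex polish: solve through the p most nearly interpolated rows and
# check the LAD subgradient condition |t| <= 1 on the basis multipliers.
lad_polish <- function(xk, y, b, r) {
  n <- nrow(xk); p <- ncol(xk)
  out <- list(coef = b, residuals = r, objective = sum(abs(r)), certified = FALSE)
  ord <- order(abs(r))
  basis <- integer(0)
  for (i in ord) {
    cand <- c(basis, i)
    if (qr(xk[cand, , drop = FALSE])$rank == length(cand)) basis <- cand
    if (length(basis) == p) break
  }
  if (length(basis) < p) return(out)
  bp <- tryCatch(solve(xk[basis, , drop = FALSE], y[basis]),
                 error = function(e) NULL)
  if (is.null(bp)) return(out)
  rp <- y - drop(xk %*% bp)
  if (sum(abs(rp)) > out$objective + 1e-10 * (1 + out$objective)) return(out)
  out$coef <- bp; out$residuals <- rp; out$objective <- sum(abs(rp))
  nb <- setdiff(seq_len(n), basis)
  th <- tryCatch(solve(t(xk[basis, , drop = FALSE]),
                       -colSums(xk[nb, , drop = FALSE] * sign(rp[nb]))),
                 error = function(e) NULL)
  if (!is.null(th) && max(abs(th)) <= 1 + 1e-8) out$certified <- TRUE
  out
}

#' Median quantile regression with a model formula
#'
#' Formula interface over [lad_fit()]: builds the design matrix with
#' treatment contrasts (reference level = lexicographically first factor
#' level, as with [lm()]) and minimizes the sum of absolute residuals.
#'
#' @param formula Model formula.
#' @param data Data frame; character variables are treated as factors with
#'   sorted levels.
#' @param eps_final Passed to [lad_fit()].
#' @return The [lad_fit()] list, with coefficient names from the design
#'   matrix.
#' @export
median_quantile_regression <- function(formula, data, eps_final = 1e-8) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- model.matrix(attr(mf, "terms"), mf)
  if (nrow(x) <= qr(x)$rank) {
    stop("median regression needs more observations than estimable parameters",
         call. = FALSE)
  }
  lad_fit(x, y, eps_final = eps_final)
}
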