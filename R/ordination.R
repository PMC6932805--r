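#' Read a site environment table
#'
#' Reads a CSV of environmental descriptors (bioclimatic, soil) with one row
#' per site (or site-year) and one column per variable; the first column, or
#' the column named by `id_col`, holds the row identifier.
#'
#' @param path CSV path.
#' @param id_col Identifier column name or index (default: first column).
#' @return Data frame with the identifier in column `id` followed by numeric
#'   variable columns.
#' @export
read_env_table <- function(path, id_col = 1L) {
  if (!file.exists(path)) stop("environment file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(id_col)) id_col <- match(id_col, names(raw))
  if (is.na(id_col) || id_col < 1L || id_col > ncol(raw)) {
    stop("id_col not found in environment table", call. = FALSE)
  }
  out <- data.frame(id = as.character(raw[[id_col]]),
                    raw[, -id_col, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Principal component ordination of environmental variables
#'
#' Bottom-up view of environmental similarity among trial sites: variables
#' are centered and scaled to unit sample standard deviation (they mix
#' units — degrees, millimetres, soil fractions — so the correlation
#' structure is the meaningful one) and ordinated by PCA via [stats::prcomp()].
#' Missing values are mean-imputed (count logged); constant variables are
#' dropped with a warning since unit scaling is undefined for them. Each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making outputs deterministic.
#'
#' @param env Output of [read_env_table()], or any data frame with an `id`
#'   column (or rownames) plus numeric variables.
#' @param n_components Number of components to keep in `scores`/`loadings`
#'   (`NULL` keeps all). Variance proportions are always reported for all
#'   components and sum to 1.
#' @return Object of class `env_pca`: list with `scores` (rows = sites),
#'   `loadings` (rows = variables), `prop_var`, `dropped_constant`,
#'   `n_imputed`.
#' @export
ordinate_environment <- function(env, n_components = NULL) {
  if (!is.data.frame(env) || nrow(env) < 2L) {
    stop("environment table needs at least 2 rows", call. = FALSE)
  }
  ids <- if ("id" %in% names(env)) as.character(env$id) else rownames(env)
  x <- env[, setdiff(names(env), "id"), drop = FALSE]
  num <- vapply(x, is.numeric, logical(1))
  x <- as.matrix(x[, num, drop = FALSE])
  if (ncol(x) < 2L) stop("environment table needs at least 2 numeric variables",
                         call. = FALSE)
  n_imputed <- sum(is.na(x))
  if (n_imputed) {
    message("ordinate_environment: mean-imputing ", n_imputed, " missing value(s)")
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  sds <- apply(x, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  dropped_constant <- colnames(x)[const]
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(dropped_constant, collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 1L) stop("no non-constant variables left", call. = FALSE)
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-|loading| positive within each component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  prop <- p$sdev^2 / sum(p$sdev^2)
  k <- if (is.null(n_components)) ncol(p$x) else min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- ids
  structure(list(scores = scores,
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 prop_var = prop,
                 dropped_constant = dropped_constant,
                 n_imputed = n_imputed,
                 center = p$center, scale = p$scale),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  k <- min(4L, length(x$prop_var))
  cat(sprintf("env_pca: %d sites x %d variables; first %d PCs explain %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), k, 100 * sum(x$prop_var[seq_len(k)])))
  invisible(x)
}
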