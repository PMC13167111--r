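#' Sweep a (sigma_b, sigma_d) grid over an environment ensemble
#'
#' For every combination of bet-hedging spread `sigma_b` and drift rate
#' `sigma_d`, the population model is run over each environment in the
#' ensemble and the per-environment log population fold changes are
#' averaged (the log of the geometric-mean fold change). Runs that go
#' extinct leave the cell at `-Inf`, retained and flagged.
#'
#' @param envs List of `environment_series` (or numeric vectors).
#' @param sigma_b_grid,sigma_d_grid Strictly increasing parameter grids.
#' @param params A [popsim_params()] object supplying everything else
#'   (`sigma_e`, `sigma_max`, `a_min`, `beta`, bins).
#' @param n_days Run length (default: length of the shortest environment).
#' @param n0 Initial mass.
#' @return Object of class `"fitness_landscape"`: list with `value`
#'   (matrix, rows = `sigma_b_grid`, cols = `sigma_d_grid`), the grids,
#'   `n_extinct` (matrix of extinct run counts), `params`, `n_env`,
#'   `n_days`.
#' @export
sweep_landscape <- function(envs, sigma_b_grid, sigma_d_grid, params,
                            n_days = NULL, n0 = 1) {
  if (!length(envs)) stop("empty environment ensemble")
  if (is.unsorted(sigma_b_grid, strictly = TRUE) ||
      is.unsorted(sigma_d_grid, strictly = TRUE))
    stop("parameter grids must be strictly increasing")
  E <- lapply(envs, function(e) if (is.data.frame(e)) e$value else as.numeric(e))
  if (is.null(n_days)) n_days <- min(lengths(E))
  nb <- length(sigma_b_grid); nd <- length(sigma_d_grid)
  val <- matrix(NA_real_, nb, nd,
                dimnames = list(sigma_b = sigma_b_grid,
                                sigma_d = sigma_d_grid))
  nex <- matrix(0L, nb, nd)
  for (j in seq_len(nd)) {
    pj <- params
    pj$sigma_d <- sigma_d_grid[j]
    kernel <- if (pj$bounding == "ou") .ou_kernel(pj) else .drift_kernel(pj)
    for (i in seq_len(nb)) {
      pij <- pj
      pij$sigma_b <- sigma_b_grid[i]
      lfc <- vapply(E, function(e) {
        state <- init_population(pij, pij$mu_env, n0)
        log0 <- state$log_total
        for (t in seq_len(n_days)) {
          state <- step_population(state, e[t], kernel)
          if (!is.finite(state$log_total)) return(-Inf)
        }
        state$log_total - log0
      }, numeric(1L))
      nex[i, j] <- sum(!is.finite(lfc))
      val[i, j] <- mean(lfc)  # -Inf if any run went extinct
    }
  }
  structure(list(value = val, sigma_b_grid = sigma_b_grid,
                 sigma_d_grid = sigma_d_grid, n_extinct = nex,
                 params = params, n_env = length(E), n_days = n_days),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("Fitness landscape:", length(x$sigma_b_grid), "x",
      length(x$sigma_d_grid), "cells,", x$n_env, "environments,",
      x$n_days, "days\n")
  opt <- find_optimum(x)
  cat("  optimum: sigma_b =", opt[1L], " sigma_d =", opt[2L], "\n")
  invisible(x)
}

#' Normalize a landscape to [0, 1]
#'
#' `(v - min) / (max - min)` over finite cells; extinct (`-Inf`) cells map
#' to 0. Errors when all finite cells are equal.
#'
#' @param landscape A `fitness_landscape`.
#' @return The landscape with `value` rescaled and `normalized = TRUE`.
#' @export
normalize_landscape <- function(landscape) {
  v <- landscape$value
  fin <- is.finite(v)
  if (sum(fin) < 2L || diff(range(v[fin])) == 0)
    stop("degenerate normalization: need at least two distinct finite cells")
  rng <- range(v[fin])
  out <- (v - rng[1L]) / (rng[2L] - rng[1L])
  out[!fin] <- 0
  landscape$value <- out
  landscape$normalized <- TRUE
  landscape
}

#' Locate the landscape optimum
#'
#' The argmax cell; ties break toward the smallest `(sigma_b, sigma_d)`
#' lexicographically.
#'
#' @param landscape A `fitness_landscape`.
#' @return Named numeric vector `c(sigma_b, sigma_d)`.
#' @export
find_optimum <- function(landscape) {
  v <- landscape$value
  if (!any(is.finite(v))) stop("no finite cell")
  best <- max(v[is.finite(v)])
  hits <- which(v == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  c(sigma_b = landscape$sigma_b_grid[hits[1L, 1L]],
    sigma_d = landscape$sigma_d_grid[hits[1L, 2L]])
}

#' Principal components analysis across fitness landscapes
#'
#' Landscapes on an identical grid are flattened, mean-centered and
#' decomposed; components are sign-fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param landscapes List of >= 2 `fitness_landscape` objects on identical
#'   grids (all cells finite; normalize first if any runs went extinct).
#' @param n_components Number of components to return (default all).
#' @return Object of class `"landscape_pca"`: list with `loadings` (array
#'   `nb x nd x k`), `scores` (landscapes x k), `variance_fraction`
#'   (sums to 1 over all components), grids.
#' @export
pca_landscapes <- function(landscapes, n_components = NULL) {
  if (length(landscapes) < 2L) stop("need at least 2 landscapes")
  g1 <- landscapes[[1L]]
  for (l in landscapes)
    if (!identical(l$sigma_b_grid, g1$sigma_b_grid) ||
        !identical(l$sigma_d_grid, g1$sigma_d_grid))
      stop("landscapes are not on identical grids")
  X <- t(vapply(landscapes, function(l) as.numeric(l$value),
                numeric(length(g1$value))))
  if (any(!is.finite(X))) stop("non-finite landscape cells; normalize first")
  if (all(apply(X, 2L, stats::var) == 0))
    stop("identical landscapes: zero variance to decompose")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) ncol(pc$rotation) else
    min(n_components, ncol(pc$rotation))
  var_all <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {   # sign convention
    s <- sign(rot[which.max(abs(rot[, c])), c])
    if (s < 0) { rot[, c] <- -rot[, c]; sco[, c] <- -sco[, c] }
  }
  nb <- length(g1$sigma_b_grid); nd <- length(g1$sigma_d_grid)
  structure(list(
    loadings = array(rot, dim = c(nb, nd, k)),
    scores = sco,
    variance_fraction = var_all,
    sigma_b_grid = g1$sigma_b_grid, sigma_d_grid = g1$sigma_d_grid),
    class = "landscape_pca")
}

#' @export
print.landscape_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat("Landscape PCA:", nrow(x$scores), "landscapes;",
      sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * vf[1L], 100 * if (length(vf) > 1L) vf[2L] else 0))
  invisible(x)
}

#' Write / read a fitness landscape as delimited text
#'
#' The cell matrix is stored tab-separated with commented metadata lines for
#' the grids, ensemble size and run length.
#'
#' @param landscape A `fitness_landscape`.
#' @param path File path.
#' @return `write_landscape` returns `path` invisibly; `read_landscape` a
#'   `fitness_landscape` (without `params`).
#' @export
write_landscape <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sigma_b_grid: ", paste(landscape$sigma_b_grid, collapse = ",")),
    paste0("# sigma_d_grid: ", paste(landscape$sigma_d_grid, collapse = ",")),
    paste0("# n_env: ", landscape$n_env),
    paste0("# n_days: ", landscape$n_days)), con)
  utils::write.table(landscape$value, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  hdr <- readLines(path, n = 6L)
  meta <- hdr[startsWith(hdr, "# ")]
  get <- function(key) sub(paste0("^# ", key, ": ?"), "",
                           meta[startsWith(meta, paste0("# ", key, ":"))][1L])
  bg <- as.numeric(strsplit(get("sigma_b_grid"), ",")[[1L]])
  dg <- as.numeric(strsplit(get("sigma_d_grid"), ",")[[1L]])
  v <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(v) <- list(sigma_b = bg, sigma_d = dg)
  structure(list(value = v, sigma_b_grid = bg, sigma_d_grid = dg,
                 n_extinct = matrix(0L, length(bg), length(dg)),
                 params = NULL, n_env = as.integer(get("n_env")),
                 n_days = as.integer(get("n_days"))),
            class = "fitness_landscape")
}
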