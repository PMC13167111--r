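#' Two-state phenotype-switching model
#'
#' An environment flips between two states with probability `p_shift` per
#' period; a fraction `f_shift` of the population switches phenotype each
#' period. Individuals matching the environment survive with fitness
#' `w_match` for that state; mismatched individuals die. Long-run success is
#' the per-period expected log population multiplier (geometric-mean
#' fitness), and its unique maximizer is `f_shift = p_shift`, independent of
#' the match fitnesses.
#'
#' @param p_shift Probability the environment changes per period, in `[0,1]`.
#' @param f_shift Fraction of the population switching phenotype, in `[0,1]`.
#' @param w_match Length-2 positive vector of match fitnesses `(w_A, w_B)`.
#' @return Object of class `"switch_model"`.
#' @export
switch_model <- function(p_shift, f_shift, w_match = c(1, 1)) {
  if (p_shift < 0 || p_shift > 1) stop("'p_shift' must lie in [0, 1]")
  if (f_shift < 0 || f_shift > 1) stop("'f_shift' must lie in [0, 1]")
  if (length(w_match) != 2L || any(w_match <= 0))
    stop("'w_match' must be two positive fitnesses")
  structure(list(p_shift = p_shift, f_shift = f_shift, w_match = w_match),
            class = "switch_model")
}

#' Expected per-period log growth of the two-state model
#'
#' `p * log(f) + (1 - p) * log(1 - f) + mean(log(w))`, the expectation of the
#' log population multiplier with the environment at its (symmetric)
#' stationary distribution. Because the fitness term is additive, the
#' maximizer over `f` is `p` regardless of `(w_A, w_B)`.
#'
#' When `0 < p < 1` and `f` is 0 or 1, some environment path eventually
#' annihilates the population: the value is `-Inf` with attribute
#' `extinct = TRUE`.
#'
#' @param m A [switch_model()].
#' @return Expected log growth per period (possibly `-Inf`).
#' @examples
#' expected_log_growth(switch_model(0.3, 0.3))  # 0.3*log(0.3)+0.7*log(0.7)
#' @export
expected_log_growth <- function(m) {
  p <- m$p_shift; f <- m$f_shift
  wbar <- mean(log(m$w_match))
  term <- function(prob, frac) if (prob == 0) 0 else prob * log(frac)
  g <- term(p, f) + term(1 - p, 1 - f) + wbar
  if (!is.finite(g))
    return(structure(-Inf, extinct = TRUE))
  g
}

#' Optimal switching fraction
#'
#' The growth-maximizing fraction of the population that should change
#' phenotype per period equals the probability the environment changes,
#' independent of the match fitnesses.
#'
#' @param p_shift Environment change probability in `[0, 1]`.
#' @param w_match Match fitnesses (ignored by the optimum; accepted to make
#'   the fitness-independence explicit).
#' @return `p_shift`.
#' @export
optimal_shift_fraction <- function(p_shift, w_match = c(1, 1)) {
  if (p_shift < 0 || p_shift > 1) stop("'p_shift' must lie in [0, 1]")
  p_shift
}

#' Monte-Carlo growth of the two-state model
#'
#' Simulates the environment flip sequence and accumulates per-period log
#' population multipliers; serves as the stochastic oracle for
#' [expected_log_growth()]. Extinction paths (`f` of 0 or 1 meeting the
#' wrong flip) contribute `-Inf` and are reported.
#'
#' @param f,p Switching fraction and flip probability.
#' @param w Match fitnesses (length 2).
#' @param n_periods Periods per replicate.
#' @param n_reps Replicates.
#' @param seed Integer seed.
#' @return List with `mean` (mean per-period log growth over replicates),
#'   `se` (standard error across replicates), `n_extinct`.
#' @export
simulate_growth <- function(f, p, w = c(1, 1), n_periods = 10000L,
                            n_reps = 1L, seed = 1L) {
  if (n_periods < 1L) stop("'n_periods' must be >= 1")
  rs <- .rng_local(as.integer(seed))
  per_rep <- numeric(n_reps)
  last_lg <- NULL
  for (r in seq_len(n_reps)) {
    flip <- rs$unif(n_periods) < p
    env <- cumsum(c(0L, as.integer(flip)))[-1L] %% 2L + 1L
    surv <- ifelse(flip, f, 1 - f)
    lg <- log(surv * w[env])
    last_lg <- lg
    per_rep[r] <- mean(lg)
  }
  list(mean = mean(per_rep),
       se = if (n_reps > 1L) stats::sd(per_rep) / sqrt(n_reps)
            else stats::sd(last_lg) / sqrt(n_periods),
       n_extinct = sum(!is.finite(per_rep)))
}

#' N-state switching model
#'
#' Environment states follow a Markov chain with row-stochastic transition
#' matrix `P`; the population redistributes phenotypes per a row-stochastic
#' strategy matrix `S` (row i = distribution of next phenotypes for
#' individuals currently matched to state i); `w` holds per-state match
#' fitnesses, mismatch being lethal.
#'
#' @param P Environment transition matrix (rows sum to 1).
#' @param S Strategy redistribution matrix (rows sum to 1).
#' @param w Positive match-fitness vector.
#' @return Object of class `"nstate_model"`.
#' @export
nstate_model <- function(P, S, w = rep(1, nrow(P))) {
  stopifnot(is.matrix(P), is.matrix(S), nrow(P) == ncol(P),
            all(dim(P) == dim(S)), length(w) == nrow(P))
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("'P' must be row-stochastic")
  if (any(S < 0) || any(abs(rowSums(S) - 1) > 1e-9))
    stop("'S' must be row-stochastic")
  if (any(w <= 0)) stop("'w' must be positive")
  structure(list(P = P, S = S, w = w), class = "nstate_model")
}

# stationary distribution of a row-stochastic matrix (leading left eigenvector)
.stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Expected log growth of the N-state model
#'
#' `sum_i pi_i sum_j P_ij log(S_ij w_j)` with `pi` the stationary
#' distribution of `P`. Zero strategy mass on a reachable transition
#' (`S_ij = 0` where `P_ij > 0`) gives `-Inf` with attribute
#' `extinct = TRUE`. The per-row optimum is `S = P` for every positive `w`.
#'
#' @param m An [nstate_model()].
#' @return Expected log growth per period.
#' @export
nstate_log_growth <- function(m) {
  pi_ <- .stationary(m$P)
  lw <- matrix(log(m$w), nrow(m$P), ncol(m$P), byrow = TRUE)
  cell <- ifelse(m$P > 0, m$P * (log(m$S) + lw), 0)
  if (any(!is.finite(cell)))
    return(structure(-Inf, extinct = TRUE))
  sum(pi_ * rowSums(cell))
}

#' Brute-force optimal strategy over a simplex grid
#'
#' Because the growth objective decomposes over rows of `S`, each row is
#' optimized independently over a simplex grid of the stated resolution; the
#' exact optimum is `S = P` (fitness-independent), which the grid search
#' recovers to within its resolution.
#'
#' @param P Environment transition matrix.
#' @param w Match-fitness vector.
#' @param resolution Simplex grid step (e.g. 0.02).
#' @return List with `S` (the best grid strategy) and `growth`.
#' @export
nstate_optimal_strategy <- function(P, w = rep(1, nrow(P)),
                                    resolution = 0.02) {
  k <- nrow(P)
  grid <- simplex_grid(k, resolution)
  pi_ <- .stationary(P)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) {
    # row objective: sum_j P_ij log(S_ij) (the w term is constant per row)
    pos <- P[i, ] > 0
    contrib <- apply(grid, 1L, function(s)
      if (any(s[pos] == 0)) -Inf else sum(P[i, pos] * log(s[pos])))
    S[i, ] <- grid[which.max(contrib), ]
  }
  m <- nstate_model(P, S, w)
  list(S = S, growth = nstate_log_growth(m))
}

#' Enumerate a simplex grid
#'
#' All compositions of 1 into `k` parts on a grid of the given step.
#'
#' @param k Number of parts.
#' @param step Grid step (1/step must be a near-integer).
#' @return Matrix with `k` columns; rows sum to 1.
#' @export
simplex_grid <- function(k, step) {
  n <- round(1 / step)
  rec <- function(k, n) {
    if (k == 1L) return(matrix(n, 1L, 1L))
    do.call(rbind, lapply(0:n, function(i) cbind(i, rec(k - 1L, n - i))))
  }
  unname(rec(k, n) / n)
}
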