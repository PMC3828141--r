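#' Bundle samples from multiple independent runs into a chain set
#'
#' Input container for the Gelman-Rubin diagnostics: `M >= 2` chains sampled
#' on a common time grid, each sample a scalar or a d-vector.
#'
#' @param samples numeric array `M x N x d` (chains x grid times x
#'   variables) or an `M x N` matrix for a single variable.
#' @param grid sample times (ms), length `N`.
#' @param var_names optional variable names.
#' @return an object of class `"chain_set"`.
#' @export
chain_set <- function(samples, grid, var_names = NULL) {
  if (length(dim(samples)) == 2L)
    samples <- array(samples, c(dim(samples), 1L))
  stopifnot(length(dim(samples)) == 3L, dim(samples)[2] == length(grid))
  if (dim(samples)[1] < 2L) stop("need at least 2 chains")
  if (is.null(var_names))
    var_names <- paste0("v", seq_len(dim(samples)[3]))
  structure(list(M = dim(samples)[1], grid = grid, samples = samples,
                 var_names = var_names),
            class = "chain_set")
}

#' Thresholds for the potential scale reduction factor
#'
#' `PSRF_THRESHOLD_VARIANCE` (1.2) applies to the variance form of R-hat
#' computed by [psrf()]; the frequently quoted 1.1 threshold
#' (`PSRF_THRESHOLD_SQRT`) belongs to the square-root form, and squaring it
#' gives back approximately 1.2.
#' @export
PSRF_THRESHOLD_VARIANCE <- 1.2

#' @rdname PSRF_THRESHOLD_VARIANCE
#' @export
PSRF_THRESHOLD_SQRT <- 1.1

window_index <- function(grid, t) {
  which(grid > t / 2 & grid <= t)
}

#' Univariate potential scale reduction factor (variance form)
#'
#' Gelman-Rubin R-hat at analysis time `t`, computed from the `N` samples
#' per chain in the window `(t/2, t]`:
#' `W` is the mean of the per-chain sample variances, `B` is `N` times the
#' variance of the chain means, and
#' \deqn{\hat R = \frac{(N-1)/N\, W + B/N}{W}.}
#' If `W = 0` (the variable is constant within every chain, e.g. a neuron
#' that never fires) R-hat is defined as 1.
#'
#' @param chains a [chain_set()] with a single variable (or `var` selecting
#'   one).
#' @param t analysis time (ms).
#' @param var index of the variable to analyze.
#' @return R-hat (scalar, `>= (N-1)/N` whenever `W > 0`).
#' @export
psrf <- function(chains, t, var = 1L) {
  stopifnot(inherits(chains, "chain_set"))
  idx <- window_index(chains$grid, t)
  if (length(idx) < 2L) stop("window (t/2, t] must contain >= 2 samples")
  x <- chains$samples[, idx, var, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  psrf_matrix(x)
}

# x: M x N matrix of windowed samples
psrf_matrix <- function(x) {
  N <- ncol(x)
  W <- mean(apply(x, 1L, var))
  if (W == 0) return(1)
  B <- N * var(rowMeans(x))
  ((N - 1) / N * W + B / N) / W
}

#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman MPSRF over a d-vector variable:
#' \deqn{\hat R_p = \frac{N-1}{N} + \frac{M+1}{M}\,
#'       \lambda_{max}\!\left(W^{-1} B / N\right)}
#' with `W` and `B/N` the within- and between-chain covariance matrix
#' estimates on the window `(t/2, t]`.  Coordinates constant across all
#' chains are dropped (mirroring the univariate `W = 0` rule) and a ridge
#' `1e-10 * tr(W)/d` is added before inversion to regularize singular `W`.
#'
#' @inheritParams psrf
#' @param vars indices of the coordinates analyzed (default all).
#' @return multivariate R-hat (scalar).
#' @export
mpsrf <- function(chains, t, vars = seq_len(dim(chains$samples)[3])) {
  stopifnot(inherits(chains, "chain_set"))
  if (!length(vars)) stop("d = 0: no coordinates to analyze")
  idx <- window_index(chains$grid, t)
  if (length(idx) < 2L) stop("window (t/2, t] must contain >= 2 samples")
  x <- chains$samples[, idx, vars, drop = FALSE]  # M x N x d
  M <- dim(x)[1]; N <- dim(x)[2]
  keep <- apply(x, 3L, function(sl) stats::sd(as.numeric(sl)) > 0)
  if (!any(keep)) return(1)
  x <- x[, , keep, drop = FALSE]
  d <- dim(x)[3]
  W <- matrix(0, d, d)
  means <- matrix(0, M, d)
  for (m in seq_len(M)) {
    xm <- matrix(x[m, , ], N, d)
    W <- W + stats::cov(xm)
    means[m, ] <- colMeans(xm)
  }
  W <- W / M
  Bn <- stats::cov(means)                 # = B / N
  W <- W + diag(1e-10 * sum(diag(W)) / d, d)
  lam <- max(Re(eigen(solve(W, Bn), only.values = TRUE)$values))
  (N - 1) / N + (M + 1) / M * lam
}

#' R-hat as a function of analysis time
#'
#' Evaluates [psrf()] (per variable) and optionally [mpsrf()] (over all
#' variables jointly) on a set of analysis times.
#'
#' @param chains a [chain_set()].
#' @param times analysis times; default: the second half of the grid.
#' @param multivariate also compute the joint MPSRF.
#' @return object of class `"psrf_curve"`: list with `times`, matrix `R`
#'   (times x variables), summary columns `mean` and `worst`, and
#'   `R_multi` if requested.
#' @export
psrf_curve <- function(chains, times = NULL, multivariate = FALSE) {
  if (is.null(times)) {
    g <- chains$grid
    cand <- g[vapply(g, function(t) length(window_index(g, t)) >= 2L,
                     logical(1))]
    times <- cand[unique(round(seq(1L, length(cand),
                                   length.out = min(25L, length(cand)))))]
  }
  d <- dim(chains$samples)[3]
  R <- vapply(times, function(t)
    vapply(seq_len(d), function(v) psrf(chains, t, v), numeric(1)),
    numeric(d))
  R <- matrix(R, nrow = length(times), ncol = d, byrow = TRUE,
              dimnames = list(NULL, chains$var_names))
  out <- list(times = times, R = R,
              mean = rowMeans(R), worst = apply(R, 1L, max),
              form = "variance")
  if (multivariate)
    out$R_multi <- vapply(times, function(t) mpsrf(chains, t), numeric(1))
  structure(out, class = "psrf_curve")
}

#' @export
print.psrf_curve <- function(x, ...) {
  cat("<psrf_curve> ", length(x$times), " analysis times, ",
      ncol(x$R), " variable(s)\n", sep = "")
  cat("  final mean R-hat:", round(x$mean[length(x$mean)], 4),
      " worst:", round(x$worst[length(x$worst)], 4), "\n")
  invisible(x)
}

#' First time after which R-hat stays below a threshold
#'
#' @param curve a [psrf_curve()] or a numeric vector of R-hat values with a
#'   `times` attribute.
#' @param threshold convergence threshold (default
#'   [PSRF_THRESHOLD_VARIANCE]); a value in the curve counts as converged if
#'   `R <= threshold`.
#' @param which summary to use for multi-variable curves: `"mean"`,
#'   `"worst"`, or `"multi"`.
#' @return the first grid time from which on all later values are below the
#'   threshold, or `NA` if the curve never settles below it.
#' @export
convergence_time <- function(curve, threshold = PSRF_THRESHOLD_VARIANCE,
                             which = c("mean", "worst", "multi")) {
  which <- match.arg(which)
  if (inherits(curve, "psrf_curve")) {
    vals <- switch(which, mean = curve$mean, worst = curve$worst,
                   multi = curve$R_multi)
    times <- curve$times
  } else {
    vals <- as.numeric(curve)
    times <- attr(curve, "times")
    if (is.null(times)) times <- seq_along(vals)
  }
  if (!length(vals)) stop("empty curve")
  above <- vals > threshold
  if (!any(above)) return(times[1L])
  last_bad <- max(which(above))
  if (last_bad == length(vals)) return(NA_real_)
  times[last_bad + 1L]
}

#' Run a multi-chain convergence experiment on a network
#'
#' Simulates `M` independent runs of the network, each started from a
#' different random initial state (random preparatory Poisson rates on the
#' network's input neurons, drawn uniformly per input neuron; for networks
#' without input neurons, random initial membrane potentials under distinct
#' preparatory seeds), samples binary simple states on a regular grid and
#' computes Gelman-Rubin curves.
#'
#' @param net a [network_model()].
#' @param M number of chains (`>= 2`).
#' @param duration run length after the preparatory phase (ms).
#' @param variable_spec list with `mode` (`"marginal"`, `"pairwise"` or
#'   `"multivariate"`), `neurons` (ids; for `"pairwise"` a 2-column matrix
#'   of id pairs), and optionally `tau` (simple-state window, ms).
#' @param seed experiment seed; chain seeds are derived from it and must be
#'   pairwise distinct.
#' @param dt simulation step (ms).
#' @param dt_sample state sampling interval (ms).
#' @param prep_duration preparatory phase length (ms).
#' @param prep_rate_range range (1/ms) preparatory input rates are drawn
#'   from, per input neuron.
#' @param chain_seeds optional explicit per-chain seeds.
#' @return a [psrf_curve()] (with `R_multi` for `"multivariate"` mode).
#' @export
run_convergence_experiment <- function(net, M, duration, variable_spec,
                                       seed = 1L, dt = 0.1, dt_sample = 10,
                                       prep_duration = 200,
                                       prep_rate_range = c(0, 0.05),
                                       chain_seeds = seed + seq_len(M)) {
  if (M < 2L) stop("need M >= 2 chains")
  if (anyDuplicated(chain_seeds))
    stop("chain seeds must be distinct (initial states must differ)")
  mode <- match.arg(variable_spec$mode,
                    c("marginal", "pairwise", "multivariate"))
  tau <- if (is.null(variable_spec$tau)) 20 else variable_spec$tau
  neurons <- variable_spec$neurons
  input_ids <- which(net$is_input)
  grid <- seq(dt_sample, duration, by = dt_sample)
  sample_ids <- if (mode == "pairwise") sort(unique(as.integer(neurons)))
                else as.integer(neurons)
  acts <- vector("list", M)
  for (m in seq_len(M)) {
    cs <- chain_seeds[m]
    if (length(input_ids)) {
      rates <- with_seed(cs * 7L + 13L,
                         runif(length(input_ids), prep_rate_range[1],
                               prep_rate_range[2]))
      prep <- prepare_initial_state(
        net, input_process(input_ids, "constant", rate = rates),
        prep_duration, prep_seed = cs, state_window = prep_duration)
      rec <- simulate_network(net, duration, dt = dt, seed = cs + 50000L,
                              prep = prep)
    } else {
      rec <- simulate_network(net, duration, dt = dt, seed = cs,
                              init_uniform = TRUE)
    }
    acts[[m]] <- activity_matrix(rec, grid, sample_ids, tau)
  }
  if (mode == "pairwise") {
    pairs <- matrix(as.integer(neurons), ncol = 2L)
    d <- nrow(pairs)
    arr <- array(0, c(M, length(grid), d))
    for (m in seq_len(M))
      for (k in seq_len(d)) {
        i <- match(pairs[k, 1L], sample_ids)
        j <- match(pairs[k, 2L], sample_ids)
        arr[m, , k] <- acts[[m]][, i] * acts[[m]][, j]
      }
    vn <- paste0("pair_", pairs[, 1L], "_", pairs[, 2L])
  } else {
    d <- length(sample_ids)
    arr <- array(0, c(M, length(grid), d))
    for (m in seq_len(M)) arr[m, , ] <- acts[[m]]
    vn <- paste0("n", sample_ids)
  }
  chains <- chain_set(arr, grid, vn)
  psrf_curve(chains, multivariate = (mode == "multivariate"))
}
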