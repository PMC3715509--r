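#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks) -- the score
#' used throughout to compare temporal importance with static predictors.
#' Nonlinear but monotone relationships between outbreak size and degree
#' make rank correlation the appropriate measure here.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return A number in \eqn{[-1, 1]}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined: constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Score a representation against temporal importance
#'
#' The Spearman rank correlation \eqn{\rho} between the expected outbreak
#' sizes \eqn{\Sigma_i} (from SIR simulation on the temporal data) and a
#' static predictor -- degree or coreness -- read off the derived network.
#' The correlation runs over *all* vertices of the original data; vertices
#' absent from the derived network get predictor value 0, so that scores
#' of representations with different vertex sets remain comparable.
#'
#' @param cs the `contact_seq` the importance table was computed on.
#' @param net a static representation of `cs` (igraph, named vertices).
#' @param imp an importance table from [importance_table()].
#' @param predictor `"degree"` or `"coreness"`.
#' @return The Spearman \eqn{\rho}.
#' @export
performance <- function(cs, net, imp, predictor = c("degree", "coreness")) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(cs, "contact_seq"))
  if (!setequal(imp$vertex, cs$labels))
    stop("importance table does not cover the vertices of the data")
  pred <- predictor_vector(cs, net, predictor)
  sigma <- imp$sigma[match(cs$labels, imp$vertex)]
  spearman_rho(sigma, pred)
}

predictor_vector <- function(cs, net, predictor) {
  vals <- if (predictor == "degree") net_degree(net) else net_coreness(net)
  out <- vals[match(cs$labels, names(vals))]
  out[is.na(out)] <- 0
  as.numeric(out)
}

#' Parameter grids for representation scans
#'
#' `window_grid()` builds the triangular grid of window endpoints
#' \eqn{0 \le t_{start} \le t_{stop} \le 1} (fractions of the sampling
#' time T) used for time-slice and ongoing networks; `expthresh_grid()`
#' the log-spaced \eqn{(\tau/T, \Omega)} grid for exponential-threshold
#' networks.
#'
#' @param n number of endpoint values per axis.
#' @return A data frame of grid points (`t_start`/`t_stop` as fractions of
#'   T, or `tau` as a multiple of T and `omega`).
#' @export
window_grid <- function(n = 21) {
  v <- seq(0, 1, length.out = n)
  g <- expand.grid(t_start = v, t_stop = v)
  g[g$t_start <= g$t_stop, , drop = FALSE]
}

#' @rdname window_grid
#' @param n_tau,n_omega points per axis.
#' @param tau_range range of \eqn{\tau} as multiples of T (log-spaced).
#' @param omega_range range of \eqn{\Omega} (log-spaced).
#' @export
expthresh_grid <- function(n_tau = 16, n_omega = 16,
                           tau_range = c(0.01, 10),
                           omega_range = c(0.01, 10)) {
  expand.grid(
    tau = exp(seq(log(tau_range[1]), log(tau_range[2]),
                  length.out = n_tau)),
    omega = exp(seq(log(omega_range[1]), log(omega_range[2]),
                    length.out = n_omega))
  )
}

build_representation <- function(cs, kind, point, T_) {
  switch(kind,
    time_slice = time_slice(cs, point$t_start * T_, point$t_stop * T_),
    ongoing = ongoing(cs, point$t_start * T_, point$t_stop * T_),
    exp_threshold = exp_threshold(cs, point$tau * T_, point$omega),
    accumulated = accumulated(cs),
    stop("unknown representation kind")
  )
}

# bootstrap replicates of per-vertex mean outbreak size from the run-level
# matrix attached to an importance table
bootstrap_sigma <- function(runs, n_boot) {
  N <- nrow(runs)
  R <- ncol(runs)
  out <- matrix(0, nrow = n_boot, ncol = N)
  for (b in seq_len(n_boot)) {
    idx <- matrix(sample.int(R, N * R, replace = TRUE), nrow = N)
    out[b, ] <- rowMeans(matrix(runs[cbind(rep(seq_len(N), R),
                                           as.vector(idx))], nrow = N))
  }
  out
}

#' Scan representation parameters for maximal performance
#'
#' Evaluates [performance()] on every point of a parameter grid and
#' reports the full \eqn{\rho} surface, the argmax point and
#' \eqn{\rho_{max}}.  Times in the grid are fractions of the sampling time
#' T; \eqn{\tau} is a multiple of T.  Degenerate points (edgeless network,
#' or constant predictor) are recorded as missing, never silently dropped.
#' Standard errors come from a nonparametric bootstrap over the per-seed
#' run-level outbreak sizes (requires `importance_table(...,
#' keep_runs = TRUE)`).
#'
#' @param cs a `contact_seq`.
#' @param imp an importance table covering `cs`.
#' @param kind `"time_slice"`, `"ongoing"`, `"exp_threshold"` or
#'   `"accumulated"`.
#' @param grid a grid data frame ([window_grid()] / [expthresh_grid()]);
#'   ignored for `"accumulated"`, which has no parameters.
#' @param predictor `"degree"` or `"coreness"`.
#' @param n_boot bootstrap resamples for standard errors (0 = no se).
#' @param rng_seed optional integer seed for the bootstrap.
#' @return An object of class `rep_scan`: list with `results` (grid plus
#'   `rho`, `se`), `best` (argmax row), `rho_max`, `rho_max_se`, `kind`
#'   and `predictor`.
#' @export
scan_representation <- function(cs, imp, kind, grid = NULL,
                                predictor = "degree", n_boot = 0,
                                rng_seed = NULL) {
  stopifnot(inherits(cs, "contact_seq"))
  kind <- match.arg(kind,
    c("time_slice", "ongoing", "exp_threshold", "accumulated"))
  if (is.null(grid)) {
    grid <- switch(kind,
      time_slice = window_grid(),
      ongoing = window_grid(),
      exp_threshold = expthresh_grid(),
      accumulated = data.frame(row.names = 1)
    )
  }
  if (nrow(grid) == 0) stop("empty grid")
  T_ <- sampling_time(cs)
  sigma <- imp$sigma[match(cs$labels, imp$vertex)]

  boot <- NULL
  if (n_boot > 0) {
    runs <- attr(imp, "runs")
    if (is.null(runs))
      stop("bootstrap standard errors need importance_table(..., keep_runs = TRUE)")
    if (!is.null(rng_seed)) set.seed(rng_seed)
    boot <- bootstrap_sigma(runs[match(cs$labels, imp$vertex), , drop = FALSE],
                            n_boot)
  }

  rho <- rep(NA_real_, nrow(grid))
  se <- rep(NA_real_, nrow(grid))
  for (p in seq_len(nrow(grid))) {
    net <- build_representation(cs, kind, grid[p, , drop = FALSE], T_)
    pred <- predictor_vector(cs, net, match.arg(predictor,
                                                c("degree", "coreness")))
    ok <- tryCatch({
      rho[p] <- spearman_rho(sigma, pred)
      TRUE
    }, error = function(e) FALSE)
    if (ok && !is.null(boot)) {
      reps <- apply(boot, 1, function(s)
        tryCatch(spearman_rho(s, pred), error = function(e) NA_real_))
      se[p] <- stats::sd(reps, na.rm = TRUE)
    }
  }
  if (all(is.na(rho)))
    stop("scan failure: rho undefined at every grid point")
  best <- which.max(rho)  # NA points never win
  out <- list(
    results = cbind(grid, rho = rho, se = se),
    best = cbind(grid[best, , drop = FALSE], rho = rho[best], se = se[best]),
    rho_max = rho[best],
    rho_max_se = se[best],
    kind = kind,
    predictor = predictor
  )
  class(out) <- "rep_scan"
  out
}

#' @export
print.rep_scan <- function(x, ...) {
  cat(sprintf("Representation scan: %s (predictor: %s)\n", x$kind,
              x$predictor))
  cat(sprintf("  %d grid points, %d undefined\n", nrow(x$results),
              sum(is.na(x$results$rho))))
  cat("  best point:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Write a scan result as a long-format table
#'
#' One row per grid point (`representation`, parameters, `rho`, `se`),
#' suitable for heatmap plotting, plus an attribute-style header line with
#' the argmax.
#'
#' @param scan a `rep_scan` object.
#' @param file output path.
#' @return `scan`, invisibly.
#' @export
write_scan <- function(scan, file) {
  df <- cbind(representation = scan$kind, scan$results)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# rho_max = %.6g at %s", scan$rho_max,
                     paste(sprintf("%s=%g",
                                   setdiff(names(scan$best), c("rho", "se")),
                                   unlist(scan$best[setdiff(names(scan$best),
                                                            c("rho", "se"))])),
                           collapse = " ")), con)
  utils::write.table(df, con, quote = FALSE, row.names = FALSE)
  invisible(scan)
}
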