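#' Synthetic survey specification
#'
#' Describes how a catch-per-unit-effort-style abundance index observes
#' a biomass trajectory: a catchability `q` scaling biomass to index
#' units, multiplicative lognormal observation noise (standard
#' deviation `noise_sd` on the log scale), a set of sampling years and
#' an RNG seed. Lognormal noise keeps the index strictly positive and
#' lets observation error grow with abundance, the usual behaviour of
#' trawl survey indices.
#'
#' @param q catchability (index units per tonne, positive).
#' @param noise_sd log-scale standard deviation of the observation
#'   noise (non-negative; 0 = noise-free).
#' @param sample_years integer-ish calendar years at which the index is
#'   observed.
#' @param seed RNG seed; draws use R's default Mersenne-Twister
#'   generator so a fixed seed reproduces the series exactly.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(q = 1, noise_sd = 0.3, sample_years, seed = 1L) {
  stopifnot(is.numeric(q), length(q) == 1L,
            is.numeric(noise_sd), length(noise_sd) == 1L,
            is.numeric(sample_years), length(sample_years) >= 1L,
            is.numeric(seed), length(seed) == 1L)
  if (q <= 0) stop("catchability 'q' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(q = q, noise_sd = noise_sd,
                 sample_years = as.numeric(sample_years),
                 seed = as.integer(seed)),
            class = "survey_spec")
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic survey series
#'
#' Observes a logistic trajectory through a survey:
#' `obs_t = q * N(t) * exp(eps)`, `eps ~ Normal(0, noise_sd^2)`,
#' deterministic under a fixed seed. The true underlying biomass is
#' retained alongside the observations for recovery testing.
#'
#' @param params a [logistic_params()] object.
#' @param spec a [survey_spec()]. Sampling years must not precede the
#'   introduction year.
#' @return A `survey_series` data frame with columns `year`,
#'   `observed_index`, `true_biomass`; generating parameters are kept
#'   in attributes `params` and `spec`.
#' @export
generate_survey <- function(params, spec) {
  stopifnot(inherits(params, "logistic_params"),
            inherits(spec, "survey_spec"))
  t <- spec$sample_years - params$t0
  if (any(t < 0)) stop("sampling years precede the introduction year")
  N <- logistic_biomass(params, t)
  eps <- if (spec$noise_sd > 0)
    with_local_seed(spec$seed, rnorm(length(t), 0, spec$noise_sd))
  else rep(0, length(t))
  out <- data.frame(year = spec$sample_years,
                    observed_index = spec$q * N * exp(eps),
                    true_biomass = N)
  attr(out, "params") <- params
  attr(out, "spec") <- spec
  class(out) <- c("survey_series", "data.frame")
  out
}

#' Generate per-cell synthetic surveys of a lattice simulation
#'
#' Applies the survey observation model independently to every cell of
#' a dispersal simulation; cell draws are taken sequentially from one
#' seeded stream so the whole table is reproducible from `spec$seed`.
#'
#' @param lspec a [lattice_spec()].
#' @param params a [logistic_params()] object.
#' @param spec a [survey_spec()].
#' @param t_max simulation horizon (years after introduction) used to
#'   cover the sampling years.
#' @return A `lattice_survey` data frame with columns `year`, `cell`,
#'   `observed_index`, `true_biomass`; the lattice trajectory is kept
#'   in the `"trajectory"` attribute.
#' @export
generate_lattice_observations <- function(lspec, params, spec,
                                          t_max = NULL) {
  stopifnot(inherits(lspec, "lattice_spec"),
            inherits(params, "logistic_params"),
            inherits(spec, "survey_spec"))
  t_obs <- spec$sample_years - params$t0
  if (any(t_obs < 0)) stop("sampling years precede the introduction year")
  if (is.null(t_max)) t_max <- max(t_obs)
  grid <- sort(unique(c(seq(0, t_max, by = 0.1), t_obs)))
  if (grid[1] != 0) grid <- c(0, grid)
  sim <- if (length(lspec$n) == 1L)
    simulate_lattice_1d(lspec, params, grid)
  else simulate_lattice_2d(lspec, params, grid)
  idx <- match(t_obs, sim$time)
  nc <- ncol(sim$biomass)
  obs <- with_local_seed(spec$seed, {
    lapply(seq_len(nc), function(i) {
      N <- sim$biomass[idx, i]
      eps <- if (spec$noise_sd > 0) rnorm(length(N), 0, spec$noise_sd)
             else rep(0, length(N))
      data.frame(year = spec$sample_years, cell = i,
                 observed_index = spec$q * N * exp(eps), true_biomass = N)
    })
  })
  out <- do.call(rbind, obs)
  attr(out, "trajectory") <- sim
  attr(out, "spec") <- spec
  class(out) <- c("lattice_survey", "data.frame")
  out
}

#' Fit the logistic model to a survey series
#'
#' Least-squares fit, on the log scale, of the closed-form logistic
#' trajectory seen through the survey model: minimises
#' `sum (log obs_t - log(q * N(t; r, N0, K)))^2` over (r, N0, q) with
#' the carrying capacity `K` held fixed at an independently supplied
#' value (K and r are only weakly jointly identified from growth-phase
#' data). Optimisation is Levenberg-Marquardt on log-transformed
#' parameters, which keeps all three positive and handles the
#' zero-residual (noise-free) case.
#'
#' @param series a [generate_survey()] result, or any data frame with
#'   `year` and `observed_index` columns (strictly positive index).
#' @param K the known carrying capacity (tonnes). Defaults to the
#'   generating value stored in `series`, when present.
#' @param t0 introduction year; defaults likewise.
#' @param start optional named list/vector of starting values for
#'   `r` and `N0` (`q` is profiled out and needs no start).
#' @return A `logistic_fit` object with `coefficients` (r, N0, q), the
#'   optimiser diagnostics, the data and fixed constants.
#'   Non-convergence stops with the optimiser's diagnostics.
#' @examples
#' sp <- survey_spec(q = 2, noise_sd = 0, sample_years = 1960:1979)
#' fit <- fit_logistic(generate_survey(victoria_params(), sp))
#' coef(fit)
#' @export
fit_logistic <- function(series, K = NULL, t0 = NULL, start = NULL) {
  stopifnot(is.data.frame(series),
            all(c("year", "observed_index") %in% names(series)))
  gen <- attr(series, "params")
  if (is.null(K)) {
    if (is.null(gen)) stop("'K' must be supplied for external series")
    K <- gen$K
  }
  if (is.null(t0)) {
    if (is.null(gen)) stop("'t0' must be supplied for external series")
    t0 <- gen$t0
  }
  keep <- series$observed_index > 0
  if (sum(keep) < 4L)
    stop("need at least 4 positive observations spanning the growth phase")
  d <- data.frame(t = series$year[keep] - t0,
                  logobs = log(series$observed_index[keep]))
  # During the exponential phase log q and log N0 enter the log-scale
  # model as a sum, so they are near-collinear; the catchability is
  # therefore profiled out (its conditional optimum is the mean
  # log-scale offset) and the search runs over (log r, log N0) only.
  log_shape <- function(lr, lN0, t) {
    N0 <- exp(lN0)
    log(K) - log1p((K - N0) / N0 * exp(-exp(lr) * t))
  }
  rss <- function(par) {
    f <- log_shape(par[1], par[2], d$t)
    res <- d$logobs - f
    res <- res - mean(res)
    sum(res^2)
  }
  if (is.null(start)) {
    sl <- stats::coef(stats::lm(logobs ~ t, data = d))
    r0 <- max(min(unname(sl[2]), 2), 0.05)
    cand <- K * 10^seq(-12, -3, by = 1.5)
    scores <- vapply(cand, function(n0) rss(c(log(r0), log(n0))),
                     numeric(1))
    start <- list(r = r0, N0 = cand[which.min(scores)])
  }
  p0 <- c(log(start$r), log(start$N0))
  opt <- stats::optim(p0, rss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, rss, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("logistic fit did not converge (optim code ", opt$convergence,
         "): ", if (is.null(opt$message)) "no message" else opt$message)
  f <- log_shape(opt$par[1], opt$par[2], d$t)
  lq <- mean(d$logobs - f)
  structure(list(coefficients = c(r = exp(opt$par[1]),
                                  N0 = exp(opt$par[2]),
                                  q = exp(lq)),
                 optim = opt, data = d, series = series, K = K, t0 = t0),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic survey fit (K fixed at", format(x$K), "t)\n")
  cat(sprintf("  r  = %.5f /yr\n  N0 = %.4g t\n  q  = %.4g index/t\n",
              x$coefficients[["r"]], x$coefficients[["N0"]],
              x$coefficients[["q"]]))
  cat(sprintf("  %d observations, RSS(log scale) = %.4g\n",
              nrow(x$data), sum(residuals(x)^2)))
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  ev <- event_years(fitted_params(object))
  structure(list(fit = object, onset_year = ev$onset_year,
                 peak_year = ev$peak_year,
                 rss = sum(residuals(object)^2)),
            class = "summary.logistic_fit")
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  implied boom onset %d, peak %d\n", x$onset_year,
              x$peak_year))
  invisible(x)
}

#' Scenario parameters implied by a survey fit
#'
#' @param object a `logistic_fit`.
#' @return A [logistic_params()] object built from the fitted (r, N0)
#'   and the fixed (K, t0).
#' @export
fitted_params <- function(object) {
  stopifnot(inherits(object, "logistic_fit"))
  logistic_params(object$coefficients[["r"]], object$K,
                  object$coefficients[["N0"]], object$t0)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$data$logobs - fitted_values_log(object)
}

fitted_values_log <- function(object) {
  cf <- object$coefficients
  log(cf[["q"]]) + log(logistic_biomass(fitted_params(object),
                                        object$data$t))
}

#' @export
fitted.logistic_fit <- function(object, ...) exp(fitted_values_log(object))

#' @export
predict.logistic_fit <- function(object, years = NULL,
                                 type = c("index", "biomass"), ...) {
  type <- match.arg(type)
  if (is.null(years)) years <- object$series$year
  N <- logistic_biomass(fitted_params(object), years - object$t0)
  if (type == "biomass") N else object$coefficients[["q"]] * N
}

#' @export
simulate.logistic_fit <- function(object, nsim = 1, seed = NULL, ...,
                                  noise_sd = NULL) {
  spec0 <- attr(object$series, "spec")
  if (is.null(noise_sd))
    noise_sd <- if (!is.null(spec0)) spec0$noise_sd else 0.3
  if (is.null(seed)) seed <- if (!is.null(spec0)) spec0$seed else 1L
  p <- fitted_params(object)
  lapply(seq_len(nsim), function(i) {
    generate_survey(p, survey_spec(q = object$coefficients[["q"]],
                                   noise_sd = noise_sd,
                                   sample_years = object$series$year,
                                   seed = seed + i - 1L))
  })
}

#' @export
plot.logistic_fit <- function(x, ...) {
  yrs <- seq(min(x$series$year), max(x$series$year), length.out = 200)
  plot(x$series$year, x$series$observed_index, log = "y",
       xlab = "Year", ylab = "Survey index", ...)
  lines(yrs, predict(x, yrs), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Write a survey series as CSV
#'
#' @param x a `survey_series` or `lattice_survey`.
#' @param path output file path.
#' @param keep_truth include the `true_biomass` column (test mode).
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(x, path, keep_truth = TRUE) {
  df <- as.data.frame(x)
  if (!keep_truth) df$true_biomass <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a survey series from CSV
#'
#' Reads a `year, observed_index[, cell][, true_biomass]` table written
#' by [write_survey_csv()]. Fitting such an external series requires
#' passing `K` and `t0` to [fit_logistic()] explicitly.
#'
#' @param path CSV file path.
#' @return A `survey_series` data frame (without generator attributes).
#' @export
read_survey_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("year", "observed_index") %in% names(df)))
  class(df) <- c("survey_series", "data.frame")
  df
}
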