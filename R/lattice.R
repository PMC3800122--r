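#' Lattice specification for dispersal models
#'
#' The lake is divided into `n` cells of equal area (a linear chain, or
#' a rectangular grid when `n` has length 2). Each cell runs logistic
#' growth towards a per-cell carrying capacity `K/n_cells` (preserving
#' lake-wide density) and exchanges biomass with its nearest neighbours
#' at migration rate `m` per year; biomass cannot leave the lattice
#' (zero-flux borders). The whole inoculum starts in `seed_cell`, the
#' northern end of the chain (or a grid corner) for the historical
#' Jinja introduction.
#'
#' @param n number of cells: a single integer for the 1-D chain or a
#'   length-2 integer vector (rows, columns) for the 2-D lattice.
#' @param m migration rate between neighbouring cells (per year,
#'   non-negative).
#' @param seed_cell index of the cell receiving all initial biomass
#'   (linear index, row-major for 2-D lattices; default 1).
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(n, m, seed_cell = 1L) {
  stopifnot(is.numeric(n), length(n) %in% 1:2, all(n >= 1), all(n == round(n)),
            is.numeric(m), length(m) == 1L, is.finite(m))
  if (m < 0) stop("migration rate 'm' must be non-negative")
  n <- as.integer(n)
  n_cells <- prod(n)
  seed_cell <- as.integer(seed_cell)
  if (length(seed_cell) != 1L || seed_cell < 1L || seed_cell > n_cells)
    stop("'seed_cell' must be a single index in 1..", n_cells)
  structure(list(n = n, n_cells = n_cells, m = m, seed_cell = seed_cell),
            class = "lattice_spec")
}

# Adjacency list (von Neumann for 2-D) as an n_cells x n_cells 0/1
# matrix; cells are in row-major order for 2-D lattices.
lattice_adjacency <- function(n) {
  if (length(n) == 1L) {
    nc <- n
    A <- matrix(0, nc, nc)
    if (nc > 1L) {
      idx <- seq_len(nc - 1L)
      A[cbind(idx, idx + 1L)] <- 1
      A[cbind(idx + 1L, idx)] <- 1
    }
    A
  } else {
    ni <- n[1]; nj <- n[2]
    nc <- ni * nj
    A <- matrix(0, nc, nc)
    id <- function(i, j) (i - 1L) * nj + j
    for (i in seq_len(ni)) for (j in seq_len(nj)) {
      if (i < ni) { A[id(i, j), id(i + 1L, j)] <- 1; A[id(i + 1L, j), id(i, j)] <- 1 }
      if (j < nj) { A[id(i, j), id(i, j + 1L)] <- 1; A[id(i, j + 1L), id(i, j)] <- 1 }
    }
    A
  }
}

simulate_lattice <- function(spec, params, t_grid, rtol, atol, y0 = NULL) {
  stopifnot(inherits(spec, "lattice_spec"),
            inherits(params, "logistic_params"), is.numeric(t_grid))
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing and start at 0")
  K_cell <- params$K / spec$n_cells
  A <- lattice_adjacency(spec$n)
  deg <- rowSums(A)
  if (is.null(y0)) {
    y0 <- numeric(spec$n_cells)
    y0[spec$seed_cell] <- params$N0
  } else {
    stopifnot(length(y0) == spec$n_cells, all(y0 >= 0))
  }
  deriv <- function(t, y, p) {
    growth <- p$r * y * (1 - y / K_cell)
    flux <- spec$m * (A %*% y - deg * y)
    list(as.vector(growth + flux))
  }
  sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("lattice ODE integration failed (lsoda istate ", diagn[1], ")")
  if (nrow(sol) < length(t_grid))
    stop("lattice ODE integration stopped early")
  biomass <- unname(sol[, -1, drop = FALSE])
  structure(list(time = unname(sol[, 1]), biomass = biomass,
                 spec = spec, params = params, K_cell = K_cell),
            class = "lattice_trajectory")
}

#' Simulate the 1-D dispersal chain
#'
#' Integrates the coupled system
#' `dN_i/dt = r N_i (1 - N_i/K_cell) + m * sum_neighbours (N_j - N_i)`
#' on a linear chain of cells with zero-flux ends, all initial biomass
#' in the seed cell.
#'
#' @param spec a [lattice_spec()] with scalar `n`.
#' @param params a [logistic_params()] object (K is the lake-wide
#'   total; per-cell capacity is `K/n`).
#' @param t_grid monotone time grid starting at 0 (years since
#'   introduction).
#' @param rtol,atol integrator tolerances.
#' @param y0 optional vector of initial per-cell biomasses overriding
#'   the single-seed-cell default (e.g. `rep(N0/n, n)` for an
#'   equal-partition run).
#' @return A `lattice_trajectory`: list with `time`, a time-by-cell
#'   `biomass` matrix, the spec, params and `K_cell`.
#' @examples
#' tr <- simulate_lattice_1d(lattice_spec(3, 0.005), victoria_params(),
#'                           seq(0, 40, by = 0.1))
#' cell_event_years(tr)
#' @export
simulate_lattice_1d <- function(spec, params, t_grid,
                                rtol = 1e-10, atol = 1e-12, y0 = NULL) {
  if (length(spec$n) != 1L)
    stop("'spec' describes a 2-D lattice; use simulate_lattice_2d()")
  simulate_lattice(spec, params, t_grid, rtol, atol, y0)
}

#' Simulate the 2-D dispersal lattice
#'
#' As [simulate_lattice_1d()] but on a rectangular grid with
#' 4-neighbour (von Neumann) coupling and zero-flux borders. Cells are
#' stored in row-major order.
#'
#' @inheritParams simulate_lattice_1d
#' @param spec a [lattice_spec()] with length-2 `n`.
#' @return A `lattice_trajectory`.
#' @export
simulate_lattice_2d <- function(spec, params, t_grid,
                                rtol = 1e-10, atol = 1e-12, y0 = NULL) {
  if (length(spec$n) != 2L)
    stop("'spec' describes a 1-D chain; use simulate_lattice_1d()")
  simulate_lattice(spec, params, t_grid, rtol, atol, y0)
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  dims <- if (length(x$spec$n) == 1L) sprintf("%d-cell chain", x$spec$n)
          else sprintf("%dx%d lattice", x$spec$n[1], x$spec$n[2])
  cat(sprintf("Lattice trajectory: %s, m = %g /yr, %d time points\n",
              dims, x$spec$m, length(x$time)))
  cat(sprintf("  K per cell %.4g t; total biomass %.4g t at end\n",
              x$K_cell, sum(x$biomass[length(x$time), ])))
  invisible(x)
}

#' @export
as.data.frame.lattice_trajectory <- function(x, ...) {
  nc <- ncol(x$biomass)
  data.frame(time = rep(x$time, nc),
             year = rep(x$params$t0 + x$time, nc),
             cell = rep(seq_len(nc), each = length(x$time)),
             biomass = as.vector(x$biomass))
}

#' @export
plot.lattice_trajectory <- function(x, ...) {
  matplot(x$params$t0 + x$time, x$biomass, type = "l", lty = 1,
          xlab = "Year", ylab = "Biomass per cell (t)", ...)
  abline(h = 0.05 * x$K_cell, lty = 3, col = gray(0.4))
  invisible(x)
}

# First time a cell series crosses `threshold`, by linear interpolation
# between grid points; NA if never crossed.
first_crossing <- function(time, series, threshold) {
  above <- series >= threshold
  if (!any(above)) return(NA_real_)
  k <- which(above)[1]
  if (k == 1L) return(time[1])
  t0 <- time[k - 1L]; t1 <- time[k]
  y0 <- series[k - 1L]; y1 <- series[k]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Per-cell boom onset and peak years
#'
#' Detects, for every lattice cell, the calendar years in which biomass
#' first exceeds `onset_fraction` and `peak_fraction` of the per-cell
#' carrying capacity (thresholds scale with cell area so they represent
#' the same density criterion as the lake-wide model). Cells that never
#' reach a threshold within the simulated window get `NA`.
#'
#' @param traj a `lattice_trajectory` from [simulate_lattice_1d()] or
#'   [simulate_lattice_2d()].
#' @param conv an [event_convention()].
#' @return A `cell_event_table` data frame with columns `cell` (and
#'   `row`, `col` for 2-D lattices), `onset_year`, `peak_year`.
#' @export
cell_event_years <- function(traj, conv = event_convention()) {
  stopifnot(inherits(traj, "lattice_trajectory"),
            inherits(conv, "event_convention"))
  nc <- ncol(traj$biomass)
  t0 <- traj$params$t0
  onset <- peak <- integer(nc)
  for (i in seq_len(nc)) {
    t_on <- first_crossing(traj$time, traj$biomass[, i],
                           conv$onset_fraction * traj$K_cell)
    t_pk <- first_crossing(traj$time, traj$biomass[, i],
                           conv$peak_fraction * traj$K_cell)
    onset[i] <- if (is.na(t_on)) NA_integer_ else
      as.integer(conv$year_rule(t0 + t_on))
    peak[i] <- if (is.na(t_pk)) NA_integer_ else
      as.integer(conv$year_rule(t0 + t_pk))
  }
  out <- data.frame(cell = seq_len(nc), onset_year = onset, peak_year = peak)
  if (length(traj$spec$n) == 2L) {
    nj <- traj$spec$n[2]
    out$row <- (out$cell - 1L) %/% nj + 1L
    out$col <- (out$cell - 1L) %% nj + 1L
    out <- out[, c("cell", "row", "col", "onset_year", "peak_year")]
  }
  class(out) <- c("cell_event_table", "data.frame")
  out
}

#' Classify a spread pattern as wave or homogeneous
#'
#' A colonisation wave is declared when per-cell boom onsets are spread
#' over at least two calendar years across the lattice; when all cells
#' boom within a year of each other the spread is homogeneous.
#'
#' @param cell_events a [cell_event_years()] table; all cells must have
#'   an onset year.
#' @return `"wave"` or `"homogeneous"`.
#' @export
classify_wave <- function(cell_events) {
  stopifnot(inherits(cell_events, "data.frame"),
            "onset_year" %in% names(cell_events))
  on <- cell_events$onset_year
  if (anyNA(on))
    stop("classification undefined: some cells never reach the onset threshold")
  if (diff(range(on)) >= 2L) "wave" else "homogeneous"
}

# Continuous onset crossing time (years since t0) for one cell of a
# 1-D chain at migration rate m; simulated on a fine grid.
chain_onset_times <- function(n, m, params, conv, t_max = 120, dt = 0.05) {
  spec <- lattice_spec(n, m)
  tr <- simulate_lattice_1d(spec, params, seq(0, t_max, by = dt),
                            rtol = 1e-9, atol = 1e-12)
  thr <- conv$onset_fraction * tr$K_cell
  vapply(seq_len(n), function(i) first_crossing(tr$time, tr$biomass[, i], thr),
         numeric(1))
}

#' Calibrate the migration rate of the 1-D chain
#'
#' Searches for a migration rate `m` such that the boom onset in the
#' last (southernmost) cell lands in `target_last_onset` while the
#' first (seed) cell still booms in `target_first_onset` -- i.e. `m` is
#' large enough to carry the wave across the lake on time yet small
#' enough not to dilute the seed cell and delay its boom. Root-finding
#' (bisection via [stats::uniroot()]) on the continuous last-cell
#' crossing time aims at the middle of the target year; if the floored
#' first-cell year then misses its target, the whole interval of `m`
#' values consistent with the last-cell year is scanned before the
#' calibration is declared infeasible. Infeasibility is a returned
#' status, not an error.
#'
#' @param n number of cells in the chain (>= 2).
#' @param target_first_onset,target_last_onset calendar years the first
#'   and last cells must boom in (defaults 1979 and 1984, the observed
#'   north and south onsets).
#' @param params a [logistic_params()] object.
#' @param conv an [event_convention()].
#' @param m_max upper end of the search bracket (per year).
#' @return An `m_calibration` list: `feasible` (logical), `m` (the
#'   calibrated rate, or NA), `first_onset`, `last_onset` (achieved
#'   years at `m`), and `n`.
#' @examples
#' \donttest{
#' calibrate_m(3, params = victoria_params())  # m near 0.11
#' }
#' @export
calibrate_m <- function(n, target_first_onset = 1979,
                        target_last_onset = 1984,
                        params = victoria_params(),
                        conv = event_convention(), m_max = 20) {
  stopifnot(n >= 2, n == round(n))
  n <- as.integer(n)
  t0 <- params$t0
  last_cross <- function(m) chain_onset_times(n, m, params, conv)[n]
  # Continuous last-cell crossing target: middle of the target year.
  aim <- function(m, target) {
    tc <- last_cross(m)
    if (is.na(tc)) return(1e6)  # never crosses: treat as very late
    tc - (target - t0)
  }
  mid <- target_last_onset + 0.5
  f_lo <- aim(1e-6, mid)
  f_hi <- aim(m_max, mid)
  result <- function(feasible, m) {
    if (feasible) {
      ot <- chain_onset_times(n, m, params, conv)
      yrs <- as.integer(conv$year_rule(t0 + ot))
      structure(list(feasible = TRUE, m = m, first_onset = yrs[1],
                     last_onset = yrs[n], n = n), class = "m_calibration")
    } else {
      structure(list(feasible = FALSE, m = NA_real_,
                     first_onset = NA_integer_, last_onset = NA_integer_,
                     n = n), class = "m_calibration")
    }
  }
  check <- function(m) {
    ot <- chain_onset_times(n, m, params, conv)
    if (anyNA(ot)) return(FALSE)
    yrs <- as.integer(conv$year_rule(t0 + ot))
    yrs[1] == target_first_onset && yrs[n] == target_last_onset
  }
  # Last-cell crossing time decreases with m; bracket must straddle.
  if (f_lo < 0 || f_hi > 0) {
    # Even the bracket ends cannot put the last cell in the target
    # year's middle; still scan the compatible interval if one exists.
    m_star <- NA_real_
  } else {
    m_star <- uniroot(aim, c(1e-6, m_max), target = mid, tol = 1e-5)$root
    if (check(m_star)) return(result(TRUE, m_star))
  }
  # Scan every m that keeps the last cell inside the target year.
  g_start <- function(m) aim(m, target_last_onset + 1)   # crosses year start
  g_end <- function(m) aim(m, target_last_onset)         # crosses year end
  br <- function(g) {
    if (g(1e-6) < 0 || g(m_max) > 0) return(NA_real_)
    uniroot(g, c(1e-6, m_max), tol = 1e-5)$root
  }
  m_lo <- br(g_start)  # smallest m: last cell just inside the year
  m_hi <- br(g_end)    # largest m: last cell about to leave the year
  if (is.na(m_lo) && is.na(m_hi)) return(result(FALSE, NA))
  if (is.na(m_lo)) m_lo <- 1e-6
  if (is.na(m_hi)) m_hi <- m_max
  for (m_try in seq(m_lo, m_hi, length.out = 21)) {
    if (check(m_try)) return(result(TRUE, m_try))
  }
  result(FALSE, NA)
}

#' @export
print.m_calibration <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("Calibrated m = %.4f /yr for n = %d (onsets %d -> %d)\n",
                x$m, x$n, x$first_onset, x$last_onset))
  } else {
    cat(sprintf("Calibration infeasible for n = %d:\n", x$n),
        " no m keeps the seed cell on time while the far cell booms",
        "in the target year\n")
  }
  invisible(x)
}

#' Write per-cell event years as CSV
#'
#' @param x a [cell_event_years()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_events_csv <- function(x, path) {
  stopifnot(inherits(x, "cell_event_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
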