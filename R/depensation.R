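#' Depensation (Allee-type) scenario specification
#'
#' Phenomenological depensation: while biomass is below a threshold
#' `c * B_ini` the population grows at a reduced rate `f * r`; above it
#' growth proceeds at the full rate `r`. `B_ini` is the onset-indicator
#' biomass (`onset_fraction * K`, 5% of K by default), the quantity the
#' thresholds are centred around.
#'
#' @param f fraction of the growth rate in effect at low density,
#'   `0 < f <= 1` (1 = no depensation).
#' @param c threshold multiple of `B_ini`, positive.
#' @return An object of class `depensation_spec`.
#' @export
depensation_spec <- function(f, c) {
  stopifnot(is.numeric(f), length(f) == 1L, is.numeric(c), length(c) == 1L)
  if (f <= 0 || f > 1) stop("'f' must satisfy 0 < f <= 1")
  if (c <= 0) stop("'c' must be positive")
  structure(list(f = f, c = c), class = "depensation_spec")
}

# Continuous-time piecewise solution machinery. Phase 1 runs the
# logistic at rate f*r from N0 until biomass hits Bc = c*B_ini; phase 2
# re-anchors the closed form at Bc and runs at the full rate. Both
# phases share K, so the trajectory and its crossing times are exact.
depensation_phases <- function(params, spec, conv) {
  B_ini <- conv$onset_fraction * params$K
  Bc <- spec$c * B_ini
  if (Bc >= params$K)
    stop("depensation threshold c * B_ini reaches carrying capacity; ",
         "the reduced-growth phase never ends")
  p1 <- logistic_params(params$r * spec$f, params$K, params$N0, params$t0)
  if (Bc <= params$N0) {
    list(t_switch = 0, Bc = params$N0, phase1 = p1, params = params)
  } else {
    list(t_switch = crossing_time(p1, Bc), Bc = Bc, phase1 = p1,
         params = params)
  }
}

# Crossing time of biomass B under the two-phase model (years since t0).
depensated_crossing_time <- function(params, spec, conv, B) {
  ph <- depensation_phases(params, spec, conv)
  if (B <= ph$Bc) {
    crossing_time(ph$phase1, B)
  } else {
    p2 <- logistic_params(params$r, params$K, ph$Bc, params$t0)
    ph$t_switch + crossing_time(p2, B)
  }
}

#' Two-phase depensated logistic trajectory
#'
#' Evaluates the exact piecewise closed form of the depensated model on
#' a time grid: reduced-rate logistic below the threshold, full-rate
#' logistic (re-anchored at the switch biomass) above it. The
#' trajectory is continuous and reduces to the plain logistic when
#' `f = 1`.
#'
#' @param params a [logistic_params()] object.
#' @param spec a [depensation_spec()].
#' @param t_grid monotone time grid starting at 0 (years since
#'   introduction).
#' @param conv an [event_convention()] (supplies `B_ini`).
#' @return A `perch_trajectory` data frame.
#' @export
depensated_trajectory <- function(params, spec, t_grid,
                                  conv = event_convention()) {
  stopifnot(inherits(params, "logistic_params"),
            inherits(spec, "depensation_spec"),
            inherits(conv, "event_convention"))
  ph <- depensation_phases(params, spec, conv)
  N <- numeric(length(t_grid))
  early <- t_grid <= ph$t_switch
  N[early] <- logistic_biomass(ph$phase1, t_grid[early])
  if (any(!early)) {
    p2 <- logistic_params(params$r, params$K, ph$Bc, params$t0)
    N[!early] <- logistic_biomass(p2, t_grid[!early] - ph$t_switch)
  }
  new_perch_trajectory(t_grid, N, params)
}

#' Event years under depensation
#'
#' Onset and peak calendar years of the two-phase depensated model,
#' under the same threshold fractions and year rule as the plain model.
#' Phase-1 duration and both crossings are computed in closed form.
#'
#' @inheritParams depensated_trajectory
#' @return An `event_years` object.
#' @examples
#' depensated_event_years(victoria_params(), depensation_spec(0.9, 1))
#' # onset 1982, peak 1990
#' @export
depensated_event_years <- function(params, spec, conv = event_convention()) {
  stopifnot(inherits(params, "logistic_params"),
            inherits(spec, "depensation_spec"),
            inherits(conv, "event_convention"))
  t_on <- depensated_crossing_time(params, spec, conv,
                                   conv$onset_fraction * params$K)
  t_pk <- depensated_crossing_time(params, spec, conv,
                                   conv$peak_fraction * params$K)
  if (!is.finite(t_on) || !is.finite(t_pk))
    stop("depensated model never reaches the event threshold ",
         "(non-terminating scenario)")
  new_event_years(conv$year_rule(params$t0 + t_on),
                  conv$year_rule(params$t0 + t_pk), t_on, t_pk)
}

#' Grid of depensation scenarios
#'
#' Computes onset and peak years over a factorial grid of depensation
#' strengths `f` and threshold multiples `c`, the scenario layout used
#' to ask how strong and how long-lived a low-density growth penalty
#' must be to delay the boom.
#'
#' @param params a [logistic_params()] object.
#' @param f_values growth-rate fractions (default the tested
#'   1, 0.9, 0.8, 0.7, 0.5).
#' @param c_values threshold multiples of `B_ini` (default 0.5, 1, 2).
#' @param conv an [event_convention()].
#' @return A `depensation_grid` data frame with columns `f`, `c`,
#'   `onset_year`, `peak_year`.
#' @export
depensation_grid <- function(params,
                             f_values = c(1, 0.9, 0.8, 0.7, 0.5),
                             c_values = c(0.5, 1, 2),
                             conv = event_convention()) {
  if (!length(f_values) || !length(c_values))
    stop("'f_values' and 'c_values' must be non-empty")
  grid <- expand.grid(f = f_values, c = c_values,
                      KEEP.OUT.ATTRS = FALSE)
  ev <- lapply(seq_len(nrow(grid)), function(i) {
    depensated_event_years(params, depensation_spec(grid$f[i], grid$c[i]),
                           conv)
  })
  grid$onset_year <- vapply(ev, `[[`, integer(1), "onset_year")
  grid$peak_year <- vapply(ev, `[[`, integer(1), "peak_year")
  class(grid) <- c("depensation_grid", "data.frame")
  grid
}

#' Write a depensation grid in the stacked table layout
#'
#' One row block per threshold multiple `c`, one column per `f`, with
#' the onset year on the first line of each cell block and the peak
#' year beneath it.
#'
#' @param grid a [depensation_grid()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_depensation_csv <- function(grid, path) {
  stopifnot(inherits(grid, "depensation_grid"))
  f_values <- sort(unique(grid$f), decreasing = TRUE)
  c_values <- sort(unique(grid$c))
  rows <- list()
  for (cc in c_values) {
    sub <- grid[grid$c == cc, ]
    sub <- sub[match(f_values, sub$f), ]
    rows[[length(rows) + 1L]] <-
      c(threshold = sprintf("%g%% B_ini", 100 * cc), event = "onset",
        setNames(as.character(sub$onset_year), sprintf("f_%g", f_values)))
    rows[[length(rows) + 1L]] <-
      c(threshold = "", event = "peak",
        setNames(as.character(sub$peak_year), sprintf("f_%g", f_values)))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
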