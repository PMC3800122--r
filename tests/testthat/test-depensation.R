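test_that("no depensation (f = 1) recovers the plain logistic exactly", {
  spec <- depensation_spec(1, 1)
  g <- seq(0, 40, by = 0.5)
  expect_equal(depensated_trajectory(victoria, spec, g)$biomass,
               logistic_biomass(victoria, g))
  ev <- depensated_event_years(victoria, spec)
  base <- event_years(victoria)
  expect_identical(ev$onset_year, base$onset_year)
  expect_identical(ev$peak_year, base$peak_year)
})

test_that("piecewise closed form matches a switching-rate ODE integration", {
  # independent oracle: integrate dN/dt with the rate switching at the
  # threshold, and compare to the closed-form piecewise trajectory
  spec <- depensation_spec(0.8, 1)
  B_switch <- 1 * 0.05 * victoria$K
  deriv <- function(t, y, p) {
    r_eff <- if (y < B_switch) 0.8 * p$r else p$r
    list(r_eff * y * (1 - y / p$K))
  }
  g <- seq(0, 45, by = 0.25)
  num <- deSolve::ode(c(N = victoria$N0), g, deriv, victoria,
                      rtol = 1e-11, atol = 1e-13)
  tr <- depensated_trajectory(victoria, spec, g)
  expect_equal(tr$biomass, unname(num[, "N"]), tolerance = 1e-6)
})

test_that("phase-1 duration follows the reduced-rate closed form", {
  # with f = 0.5 and c = 1, time to reach B_ini is the crossing time
  # of a logistic running at r/2
  spec <- depensation_spec(0.5, 1)
  ev <- depensated_event_years(victoria, spec)
  half_rate <- logistic_params(0.5 * 0.73, victoria$K, victoria$N0, 1954)
  expect_equal(ev$onset_time, crossing_time(half_rate, 0.05 * victoria$K),
               tolerance = 1e-12)
  expect_gt(ev$onset_time, 51)
})

test_that("depensation grid matches the published years within one year", {
  grid <- depensation_grid(victoria, depensation_f_levels,
                          depensation_c_levels)
  for (i in seq_along(depensation_c_levels)) {
    for (j in seq_along(depensation_f_levels)) {
      row <- grid[grid$f == depensation_f_levels[j] &
                    grid$c == depensation_c_levels[i], ]
      expect_lte(abs(row$onset_year - published_depensation_onset[i, j]), 1)
      expect_lte(abs(row$peak_year - published_depensation_peak[i, j]), 1)
    }
  }
  # pinned cells reproduced exactly
  cell <- function(f, c) grid[grid$f == f & grid$c == c, ]
  expect_identical(cell(1, 1)$onset_year, 1979L)
  expect_identical(cell(1, 1)$peak_year, 1987L)
  expect_identical(cell(0.9, 1)$onset_year, 1982L)
  expect_identical(cell(0.8, 0.5)$onset_year, 1985L)
  expect_identical(cell(0.8, 0.5)$peak_year, 1993L)
})

test_that("onset year is monotone in depensation strength and duration", {
  grid <- depensation_grid(victoria, c(1, 0.9, 0.7, 0.5), c(0.5, 1, 2))
  for (cc in unique(grid$c)) {
    sub <- grid[grid$c == cc, ]
    sub <- sub[order(-sub$f), ]   # decreasing f = stronger depensation
    expect_true(all(diff(sub$onset_year) >= 0))
  }
  # longer-lived depensation (larger c) never hastens the onset
  for (ff in unique(grid$f)) {
    sub <- grid[grid$f == ff, ]
    sub <- sub[order(sub$c), ]
    expect_true(all(diff(sub$onset_year) >= 0))
  }
})

test_that("when depensation ends by the onset threshold the boom keeps its width", {
  # once the reduced-growth phase is over before (or exactly at) the
  # onset threshold, the onset-to-peak interval is the full-rate value
  # (1/r) log(0.95^2/0.05^2) in continuous time; the floored calendar
  # width is then 8 or 9 depending on where the onset falls in its year
  base_gap <- log(0.95^2 / 0.05^2) / victoria$r
  for (f in c(0.9, 0.8, 0.5)) for (cc in c(0.5, 1)) {
    ev <- depensated_event_years(victoria, depensation_spec(f, cc))
    expect_equal(ev$peak_time - ev$onset_time, base_gap, tolerance = 1e-10)
    expect_true((ev$peak_year - ev$onset_year) %in% c(8L, 9L))
  }
  # a threshold above the onset indicator stretches the interval
  ev2 <- depensated_event_years(victoria, depensation_spec(0.8, 2))
  expect_gt(ev2$peak_time - ev2$onset_time, base_gap)
})

test_that("degenerate depensation specs are rejected", {
  expect_error(depensation_spec(0, 1), "f")
  expect_error(depensation_spec(1.2, 1), "f")
  expect_error(depensation_spec(0.8, -1), "c")
  # threshold at/above K never ends the reduced phase
  expect_error(depensated_event_years(victoria, depensation_spec(0.8, 20)),
               "carrying capacity")
})

test_that("grid CSV export uses the stacked onset/peak layout", {
  grid <- depensation_grid(victoria)
  path <- withr::local_tempfile(fileext = ".csv")
  write_depensation_csv(grid, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_identical(nrow(tab), 6L)        # 3 thresholds x (onset, peak)
  expect_identical(tab$event, rep(c("onset", "peak"), 3))
  expect_identical(tab[tab$event == "onset", "f_1"], rep(1979L, 3))
})
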