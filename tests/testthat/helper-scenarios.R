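# Shared fixtures: the two historical scenarios and a convention object.
victoria <- victoria_params()
kyoga <- kyoga_params()
conv <- event_convention()

# Independent crossing-time oracle: bisection on the numerically
# integrated ODE trajectory (never uses the closed-form inversion).
ode_crossing_oracle <- function(params, B, t_max = 80) {
  f <- function(t) {
    if (t == 0) return(params$N0 - B)
    tr <- integrate_logistic(params, c(0, t))
    tr$biomass[2] - B
  }
  uniroot(f, c(0, t_max), tol = 1e-10)$root
}

# The depensation grid of onset (top) and peak (bottom) years as
# printed in the historical reconstruction; rows are threshold
# multiples c in {0.5, 1, 2}, columns f in {1, 0.9, 0.8, 0.7, 0.5}.
published_depensation_onset <- rbind(
  c(1979, 1982, 1985, 1989, 2003),
  c(1979, 1982, 1985, 1990, 2004),
  c(1979, 1982, 1984, 1990, 2004))
published_depensation_peak <- rbind(
  c(1987, 1990, 1993, 1998, 2012),
  c(1987, 1990, 1994, 1998, 2013),
  c(1987, 1990, 1994, 1999, 2014))
depensation_f_levels <- c(1, 0.9, 0.8, 0.7, 0.5)
depensation_c_levels <- c(0.5, 1, 2)
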