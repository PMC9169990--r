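# Independent geometric oracles, kept free of the package's own
# correction formulas.

# Monte-Carlo slab-sectioning oracle: spheres of diameter D with
# centres uniform along an axis of length L; a slab [a, a+T] shows a
# profile for every sphere whose centre lies within D/2 of the slab.
# Returns the observed-profile / true-in-slab count ratio, which the
# Abercrombie overcount factor (T+D)/T should match.
slab_sectioning_ratio <- function(n_spheres, diameter, thickness,
                                  axis_length = 20 * (thickness + diameter)) {
  z <- stats::runif(n_spheres, 0, axis_length)
  a <- axis_length / 2  # slab well inside the axis, no edge effects
  observed <- sum(z >= a - diameter / 2 & z <= a + thickness + diameter / 2)
  true_in_slab <- n_spheres * thickness / axis_length
  observed / true_in_slab
}

# Closed-form cylinder phantom: straight tubules of known total length
# and diameter packed into a known volume. Returns the inputs the
# length estimator should invert exactly.
cylinder_phantom <- function(total_length_m, diameter_um, volume_ml) {
  tubule_volume_um3 <- pi * (diameter_um / 2)^2 * total_length_m * 1e6
  fraction <- tubule_volume_um3 / (volume_ml * 1e12)
  stopifnot(fraction <= 1)
  list(volume_ml = volume_ml, fraction = fraction, diameter_um = diameter_um,
       length_m = total_length_m)
}
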