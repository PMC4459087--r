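# shared fixtures built in code

# balanced 8-taxon clock tree, all divergences <= 18 MY (unsaturated regime)
shallow_tree <- function() {
  ape::read.tree(
    text = "(((A:2,B:2):10,(C:4,D:4):8):6,((E:3,F:3):9,(G:5,H:5):7):6);"
  )
}

# two nested calibratable clades at 10 and 60 MY
two_depth_tree <- function() {
  ape::read.tree(text = "((A:10,B:10):50,(C:55,D:55):5);")
}

# independent oracle for the expected-distance law: stepwise integration of
# the slope function on a grid aligned with the window breakpoints
integrate_saturation <- function(model, t_grid, step = 0.1) {
  slope_at <- function(t) {
    if (t < model$onset) return(model$rate)
    k <- floor((t - model$onset) / model$window) + 1
    model$rate * model$decay^k
  }
  fine <- seq(0, max(t_grid), by = step)
  mids <- fine[-1] - step / 2
  d <- c(0, cumsum(vapply(mids, slope_at, numeric(1)) * step))
  d[match(round(t_grid / step), round(fine / step))]
}
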