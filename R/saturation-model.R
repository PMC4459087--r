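#' Piecewise-linear substitution saturation model
#'
#' Constructs a model of expected percent genetic distance as a function of
#' divergence time under progressive substitution saturation. Distance grows
#' linearly at a background rate up to an onset time, after which the slope is
#' reduced by a constant factor in each successive time window: in the k-th
#' window after onset the slope is `rate * decay^k`. With the defaults (1%
#' pairwise distance per MY, onset 20 MY, a 50% slope reduction every 10 MY)
#' the expected distance at 30 MY is 25% and at 60 MY is 29.375%.
#'
#' @param rate Background rate, in percent pairwise distance per MY. Must be
#'   positive.
#' @param onset Divergence time (MY) at which saturation begins. Non-negative.
#' @param decay Per-window slope multiplier, in (0, 1]. `decay = 1` disables
#'   saturation.
#' @param window Width (MY) of each post-onset window. Positive.
#'
#' @return An object of class `saturation_model`.
#' @examples
#' m <- saturation_model()
#' expected_distance(m, c(10, 30, 60))
#' @export
saturation_model <- function(rate = 1, onset = 20, decay = 0.5, window = 10) {
  stopifnot(
    is.numeric(rate), length(rate) == 1, rate > 0,
    is.numeric(onset), length(onset) == 1, onset >= 0,
    is.numeric(decay), length(decay) == 1, decay > 0, decay <= 1,
    is.numeric(window), length(window) == 1, window > 0
  )
  structure(
    list(rate = rate, onset = onset, decay = decay, window = window),
    class = "saturation_model"
  )
}

#' @export
print.saturation_model <- function(x, ...) {
  cat("Piecewise-linear saturation model\n")
  cat(sprintf("  background rate : %g %% distance / MY\n", x$rate))
  cat(sprintf("  saturation onset: %g MY\n", x$onset))
  cat(sprintf("  slope multiplier: %g per %g-MY window\n", x$decay, x$window))
  invisible(x)
}

#' Expected percent distance at a divergence time
#'
#' Evaluates the model's expected pairwise genetic distance (percent) for
#' sequences that diverged `t` MY ago. Exact closed form of the piecewise
#' linear map: continuous, strictly increasing, slope `rate` before onset and
#' `rate * decay^k` in the k-th post-onset window.
#'
#' @param model A [saturation_model()].
#' @param t Divergence time(s), MY. Non-negative.
#' @return Numeric vector of expected percent distances, same length as `t`.
#' @examples
#' expected_distance(saturation_model(), 30) # 25
#' @export
expected_distance <- function(model, t) {
  stopifnot(inherits(model, "saturation_model"), is.numeric(t))
  if (any(t < 0)) stop("divergence time `t` must be non-negative", call. = FALSE)
  r <- model$rate; t0 <- model$onset; f <- model$decay; w <- model$window
  pre <- r * pmin(t, t0)
  s <- pmax(t - t0, 0)
  if (f == 1) return(pre + r * s)
  k <- floor(s / w) # completed post-onset windows
  # geometric sum over completed windows + partial current window (slope r f^(k+1))
  post <- r * w * f * (1 - f^k) / (1 - f) + r * f^(k + 1) * (s - k * w)
  pre + post
}

#' Invert the distance-time map
#'
#' Returns the unique divergence time at which the model's expected distance
#' equals `d`. Exact inverse of the piecewise-linear map; a bijection on
#' `[0, Inf)` for `decay > 0`.
#'
#' @inheritParams expected_distance
#' @param d Expected percent distance(s). Non-negative.
#' @return Divergence time(s), MY.
#' @examples
#' invert_distance(saturation_model(), 25) # 30
#' @export
invert_distance <- function(model, d) {
  stopifnot(inherits(model, "saturation_model"), is.numeric(d))
  if (any(d < 0)) stop("distance `d` must be non-negative", call. = FALSE)
  r <- model$rate; t0 <- model$onset; f <- model$decay; w <- model$window
  d0 <- r * t0 # distance accumulated at onset
  out <- d / r
  deep <- d > d0
  if (any(deep)) {
    if (f == 1) {
      out[deep] <- t0 + (d[deep] - d0) / r
    } else {
      rem <- d[deep] - d0
      # completed windows k satisfy r*w*f*(1-f^k)/(1-f) <= rem
      k <- pmax(0, floor(log(1 - rem * (1 - f) / (r * w * f)) / log(f)))
      # guard against floating point at window boundaries
      full <- function(k) r * w * f * (1 - f^k) / (1 - f)
      k <- ifelse(full(k + 1) <= rem, k + 1, k)
      k <- ifelse(full(k) > rem + 1e-12, k - 1, k)
      out[deep] <- t0 + k * w + (rem - full(k)) / (r * f^(k + 1))
    }
  }
  out
}

#' Apparent substitution rate implied by a calibration point
#'
#' The rate a strict clock would infer from a single calibration: expected
#' distance at the calibration's true age divided by that age. Equals the
#' background rate when the calibration lies in the unsaturated zone
#' (`true_age <= onset`); smaller otherwise.
#'
#' @inheritParams expected_distance
#' @param cal_age True age(s) of the calibration node, MY. Positive.
#' @return Apparent rate(s), percent distance per MY.
#' @examples
#' apparent_rate(saturation_model(), c(10, 30, 60))
#' @export
apparent_rate <- function(model, cal_age) {
  stopifnot(is.numeric(cal_age))
  if (any(cal_age <= 0)) {
    stop("calibration age must be strictly positive", call. = FALSE)
  }
  expected_distance(model, cal_age) / cal_age
}

#' Strict-clock age estimate under a single calibration
#'
#' The single-calibration estimator: expected distance at the true age divided
#' by the calibration's apparent rate. Exact for all nodes at or below the
#' saturation onset when the calibration is also unsaturated; a calibration in
#' the saturation zone overestimates young nodes, and every calibration
#' underestimates sufficiently old nodes.
#'
#' @inheritParams apparent_rate
#' @param true_t True node age(s), MY. Non-negative.
#' @return Estimated age(s), MY.
#' @examples
#' estimated_age(saturation_model(), 10, cal_age = 30) # 12
#' @export
estimated_age <- function(model, true_t, cal_age) {
  expected_distance(model, true_t) / apparent_rate(model, cal_age)
}

#' Pool a calibration set into one strict-clock rate
#'
#' Combines the expected distances at several calibration ages into a single
#' rate, either by through-origin least squares of distance on age
#' (`"origin_ls"`, age-weighted, the default) or by an unweighted mean of the
#' per-calibration apparent rates (`"mean"`).
#'
#' @inheritParams apparent_rate
#' @param cal_age Vector of calibration true ages, MY.
#' @param pooling `"origin_ls"` or `"mean"`.
#' @return A single pooled rate, percent distance per MY.
#' @examples
#' pooled_rate(saturation_model(), c(10, 60)) # ~0.50338
#' @export
pooled_rate <- function(model, cal_age, pooling = c("origin_ls", "mean")) {
  pooling <- match.arg(pooling)
  if (length(cal_age) == 0) stop("calibration set is empty", call. = FALSE)
  d <- expected_distance(model, cal_age)
  switch(pooling,
    origin_ls = sum(cal_age * d) / sum(cal_age^2),
    mean = mean(d / cal_age)
  )
}

#' Bias profile of calibrated age estimates across true ages
#'
#' For each true age, computes the strict-clock age estimate implied by the
#' calibration set (single calibration: the single-calibration estimator;
#' several: the pooled rate) and classifies the signed relative deviation as
#' underestimate (`-`), correct (`0`) or overestimate (`+`).
#'
#' @inheritParams pooled_rate
#' @param true_ages Vector of true node ages, MY. Non-empty.
#' @param tolerance Relative deviation below which an estimate is classed `0`
#'   (default 0.05, i.e. 5%).
#' @return A tibble with columns `true_age`, `estimated_age`, `deviation_pct`
#'   and `class` (factor with levels `-`, `0`, `+`).
#' @examples
#' bias_profile(saturation_model(), c(5, 15, 40), cal_age = 10)
#' @export
bias_profile <- function(model, true_ages, cal_age,
                         pooling = c("origin_ls", "mean"), tolerance = 0.05) {
  pooling <- match.arg(pooling)
  if (length(true_ages) == 0) stop("`true_ages` is empty", call. = FALSE)
  if (length(cal_age) == 0) stop("calibration set is empty", call. = FALSE)
  rate <- if (length(cal_age) == 1) {
    apparent_rate(model, cal_age)
  } else {
    pooled_rate(model, cal_age, pooling)
  }
  est <- expected_distance(model, true_ages) / rate
  dev <- ifelse(true_ages > 0, (est - true_ages) / true_ages * 100, 0)
  tibble::tibble(
    true_age = true_ages,
    estimated_age = est,
    deviation_pct = dev,
    class = deviation_class(dev, tolerance)
  )
}

#' Classify signed percent deviations
#'
#' @param deviation_pct Signed deviations, in percent.
#' @param tolerance Relative tolerance (proportion) for class `0`.
#' @return Factor with levels `-`, `0`, `+`.
#' @export
deviation_class <- function(deviation_pct, tolerance = 0.05) {
  cls <- ifelse(abs(deviation_pct) < tolerance * 100, "0",
    ifelse(deviation_pct > 0, "+", "-")
  )
  factor(cls, levels = c("-", "0", "+"))
}

#' Convert between percent distances and proportions
#'
#' @param x Numeric vector.
#' @return `pct_to_prop()` divides by 100; `prop_to_pct()` multiplies by 100.
#' @export
pct_to_prop <- function(x) x / 100

#' @rdname pct_to_prop
#' @export
prop_to_pct <- function(x) x * 100
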