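# Distance-based strict-clock dating on a fixed topology with minimum-age
# fossil calibrations: a desk-scale proxy for Bayesian node dating in the
# regime where posteriors sit at the calibration minima. Node heights come
# from mean between-clade p-distances; a single clock rate is fitted through
# the origin against the calibration ages; ages are heights over rate, with
# nonparametric bootstrap over alignment columns for confidence intervals.

# --- input normalisation -----------------------------------------------------

# Accepts a DNAbin alignment, a list of DNAbin alignments, a percent distance
# matrix, or a list of such matrices. Returns list(aln = list|NULL,
# dists = list of matrices, weights).
normalise_dating_data <- function(data, weights = NULL,
                                  correction = c("raw", "JC69")) {
  correction <- match.arg(correction)
  is_aln <- function(x) inherits(x, "DNAbin")
  if (is_aln(data)) data <- list(data)
  if (is.matrix(data) && is.numeric(data)) data <- list(data)
  stopifnot(is.list(data), length(data) >= 1)
  if (all(vapply(data, is_aln, logical(1)))) {
    dists <- lapply(data, p_distance_matrix, correction = correction)
    w <- weights %||% vapply(data, ncol, numeric(1))
    return(list(aln = data, dists = dists, weights = w))
  }
  stopifnot(all(vapply(data, function(x) is.matrix(x) && is.numeric(x), logical(1))))
  list(aln = NULL, dists = data, weights = weights %||% rep(1, length(data)))
}

combine_distances <- function(dists, weights) {
  taxa <- rownames(dists[[1]])
  acc <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_along(dists)) {
    acc <- acc + weights[i] * dists[[i]][taxa, taxa]
  }
  acc / sum(weights)
}

# --- node heights ------------------------------------------------------------

#' Strict-clock node heights from pairwise distances
#'
#' The height of each internal node is the mean pairwise percent distance
#' between tips in different child subtrees, halved (per-lineage distance
#' units). Heights are then clamped to be monotone from root to tips (a child
#' whose raw height exceeds its parent's is capped at the parent height and
#' flagged).
#'
#' @param tree A rooted `ape::phylo` topology whose tips all appear in the
#'   distance matrix.
#' @param data A percent distance matrix, `ape::DNAbin` alignment, or a list
#'   of either (loci combined by a weighted average of distances; weights
#'   default to locus lengths for alignments).
#' @param weights Optional locus weights overriding the default.
#' @param correction Distance type when computing from alignments; see
#'   [p_distance_matrix()].
#' @return A tibble with columns `node`, `clade_taxa`, `height` (percent
#'   per-lineage distance) and `clamped`.
#' @export
node_heights <- function(tree, data, weights = NULL,
                         correction = c("raw", "JC69")) {
  stopifnot(inherits(tree, "phylo"))
  nd <- normalise_dating_data(data, weights, match.arg(correction))
  dmat <- combine_distances(nd$dists, nd$weights)
  missing <- setdiff(tree$tip.label, rownames(dmat))
  if (length(missing) > 0) {
    stop("taxa missing from distance data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  node_heights_from_matrix(tree, dmat)
}

node_heights_from_matrix <- function(tree, dmat) {
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  tipsets <- lapply(seq_len(ntip + tree$Nnode), function(n) {
    if (n <= ntip) tree$tip.label[n] else ape::extract.clade(tree, n)$tip.label
  })
  children <- split(tree$edge[, 2], tree$edge[, 1])
  raw <- vapply(nodes, function(n) {
    kids <- children[[as.character(n)]]
    sets <- tipsets[kids]
    tot <- 0; cnt <- 0
    for (i in seq_len(length(sets) - 1)) {
      for (j in seq(i + 1, length(sets))) {
        block <- dmat[sets[[i]], sets[[j]], drop = FALSE]
        tot <- tot + sum(block); cnt <- cnt + length(block)
      }
    }
    tot / cnt / 2
  }, numeric(1))
  # clamp: preorder walk, cap each child at its parent's height
  h <- stats::setNames(raw, nodes)
  clamped <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  edge_ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(edge_ord))) {
    parent <- as.character(edge_ord[i, 1]); child <- as.character(edge_ord[i, 2])
    if (edge_ord[i, 2] > ntip && h[child] > h[parent]) {
      h[child] <- h[parent]
      clamped[child] <- TRUE
    }
  }
  tibble::tibble(
    node = nodes,
    clade_taxa = vapply(nodes, function(n) paste(sort(tipsets[[n]]), collapse = ";"),
                        character(1)),
    height = unname(h),
    clamped = unname(clamped)
  )
}

# --- rate calibration --------------------------------------------------------

# negative log prior density of a node age under one calibration row
calibration_penalty <- function(age, min_age, shape, spread) {
  switch(shape,
    lognormal = {
      x <- age - min_age
      # offset lognormal: sdlog = spread, meanlog set so the 95% quantile of
      # the offset is ~12.5 MY at spread = 1 (a soft maximum 10-15 MY past
      # the minimum)
      meanlog <- log(12.5) - stats::qnorm(0.95) * spread
      if (x <= 0) 1e4 * (1 - x) else -stats::dlnorm(x, meanlog, spread, log = TRUE)
    },
    normal = -stats::dnorm(age, mean = min_age, sd = spread, log = TRUE),
    uniform = {
      if (age < min_age) 10 + 1e3 * (min_age - age)^2
      else if (age > spread) 10 + 1e3 * (age - spread)^2
      else 0
    },
    stop("unknown calibration shape: ", shape, call. = FALSE)
  )
}

#' Fit a strict-clock rate to calibrated node heights
#'
#' Resolves each calibration clade to a node (MRCA semantics), then fits one
#' rate on the pairwise scale (percent pairwise distance per MY, matching
#' [saturation_model()]'s rate). `mode = "point_min"` treats each minimum age
#' as the node's age and fits through-origin least squares of heights on
#' minima — the proxy for posteriors that sit at the prior minima.
#' `mode = "hard_min"` takes the largest rate under which no calibrated node
#' falls below its minimum (the binding calibration pins the clock), mirroring
#' the hard lower bound a minimum-age prior imposes in Bayesian dating.
#' `mode = "soft"` instead minimises the summed negative log prior density of
#' the implied ages, so ages may exceed their minima according to the prior
#' `shape`/`spread`.
#'
#' @param heights A [node_heights()] tibble.
#' @param calibrations A calibration tibble as from [default_calibrations()].
#' @param tree The topology the heights were computed on.
#' @param mode `"point_min"` (default), `"hard_min"` or `"soft"`.
#' @return An object of class `clock_rate_fit`: list with `rate` (percent
#'   pairwise distance per MY), `calibrations` (per-calibration table with
#'   implied ages), and `mode`.
#' @export
calibrate_rate <- function(heights, calibrations, tree,
                           mode = c("point_min", "hard_min", "soft")) {
  mode <- match.arg(mode)
  if (is.null(calibrations) || nrow(calibrations) == 0) {
    stop("at least one calibration is required to fit a clock rate",
         call. = FALSE)
  }
  nodes <- vapply(
    calibrations$clade_taxa,
    function(cl) clade_mrca(tree, cl, require_monophyly = TRUE),
    integer(1)
  )
  h <- heights$height[match(nodes, heights$node)]
  if (anyNA(h)) stop("calibrated clade has no height entry", call. = FALSE)
  x <- calibrations$min_age
  if (any(x <= 0)) stop("calibration minimum ages must be positive", call. = FALSE)
  if (mode == "point_min") {
    rate <- 2 * sum(x * h) / sum(x^2)
  } else if (mode == "hard_min") {
    rate <- min(2 * h / x)
  } else {
    obj <- function(lograte) {
      ages <- 2 * h / exp(lograte)
      sum(mapply(calibration_penalty, ages, x,
                 calibrations$shape, calibrations$spread))
    }
    opt <- stats::optimize(obj, interval = log(c(1e-6, 1e3)))
    rate <- exp(opt$minimum)
  }
  structure(
    list(
      rate = rate,
      calibrations = tibble::tibble(
        clade = calibrations$clade,
        min_age = x,
        node = nodes,
        height = h,
        implied_age = 2 * h / rate
      ),
      mode = mode
    ),
    class = "clock_rate_fit"
  )
}

#' @export
print.clock_rate_fit <- function(x, ...) {
  cat(sprintf("Strict-clock rate fit (%s): %.5g %% pairwise distance / MY\n",
              x$mode, x$rate))
  print(x$calibrations)
  invisible(x)
}

# --- dating ------------------------------------------------------------------

#' Date all nodes of a topology from distances and fossil calibrations
#'
#' Computes node heights, fits a strict-clock rate against the calibration
#' minima, and converts heights to ages. Confidence intervals come from a
#' nonparametric bootstrap over alignment columns (resampled independently
#' within each locus; distances, heights and the rate are recomputed per
#' replicate), so they require alignment input; with distance-matrix input use
#' `bootstrap_reps = 0`.
#'
#' @inheritParams node_heights
#' @param calibrations Calibration tibble (see [default_calibrations()]).
#' @param mode Rate-fitting mode, see [calibrate_rate()].
#' @param bootstrap_reps Number of bootstrap replicates (default 100; 0 gives
#'   degenerate intervals equal to the point estimate).
#' @param seed Integer seed for the bootstrap.
#' @param combine `"concatenate"` (length-weighted average of per-locus
#'   distances before dating; default) or `"average"` (date each locus
#'   separately and average the ages with the same weights).
#' @return An object of class `dated_tree` with an `estimates` tibble (`node`,
#'   `clade_taxa`, `height`, `clamped`, `point_age`, `ci_low`, `ci_high`,
#'   `relative_ci`), the `rate_fit`, and the input `tree`. Methods: [tidy()],
#'   [glance()], `print()`, [ggplot2::autoplot()].
#' @examples
#' tr <- make_reference_chronogram()
#' d <- stylized_distances(tr)
#' dt <- date_tree(tr, d, default_calibrations(), bootstrap_reps = 0)
#' tidy(dt)
#' @export
date_tree <- function(tree, data, calibrations,
                      mode = c("point_min", "hard_min", "soft"),
                      bootstrap_reps = 100, seed = NULL, weights = NULL,
                      correction = c("raw", "JC69"),
                      combine = c("concatenate", "average")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  combine <- match.arg(combine)
  stopifnot(bootstrap_reps >= 0)
  nd <- normalise_dating_data(data, weights, correction)
  if (bootstrap_reps > 0 && is.null(nd$aln)) {
    stop("bootstrap requires alignment input; use bootstrap_reps = 0 with ",
         "distance matrices", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  point <- date_once(tree, nd$dists, nd$weights, calibrations, mode, combine)

  if (bootstrap_reps > 0) {
    boot <- replicate(bootstrap_reps, {
      dists <- lapply(nd$aln, function(a) {
        idx <- sample.int(ncol(a), replace = TRUE)
        p_distance_matrix(a[, idx], correction = correction)
      })
      date_once(tree, dists, nd$weights, calibrations, mode, combine)$ages
    })
    ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    ci_low <- ci[1, ]; ci_high <- ci[2, ]
  } else {
    ci_low <- ci_high <- point$ages
  }

  est <- point$heights
  est$point_age <- point$ages
  est$ci_low <- pmin(ci_low, point$ages)
  est$ci_high <- pmax(ci_high, point$ages)
  est$relative_ci <- ifelse(
    point$ages > 0, (est$ci_high - est$ci_low) / point$ages * 100, 0
  )
  structure(
    list(
      estimates = est[, c("node", "clade_taxa", "height", "clamped",
                          "point_age", "ci_low", "ci_high", "relative_ci")],
      rate_fit = point$fit,
      tree = tree,
      mode = mode,
      bootstrap_reps = bootstrap_reps
    ),
    class = "dated_tree"
  )
}

# one full dating pass on fixed distance matrices
date_once <- function(tree, dists, weights, calibrations, mode, combine) {
  if (combine == "concatenate" || length(dists) == 1) {
    h <- node_heights_from_matrix(tree, combine_distances(dists, weights))
    fit <- calibrate_rate(h, calibrations, tree, mode)
    ages <- 2 * h$height / fit$rate
  } else {
    per <- lapply(dists, function(d) {
      h <- node_heights_from_matrix(tree, d[tree$tip.label, tree$tip.label])
      fit <- calibrate_rate(h, calibrations, tree, mode)
      list(h = h, ages = 2 * h$height / fit$rate, fit = fit)
    })
    h <- per[[1]]$h
    agemat <- vapply(per, function(p) p$ages, numeric(nrow(h)))
    ages <- as.vector(agemat %*% (weights / sum(weights)))
    h$height <- vapply(seq_len(nrow(h)), function(i) {
      sum(vapply(per, function(p) p$h$height[i], numeric(1)) * weights) / sum(weights)
    }, numeric(1))
    h$clamped <- Reduce(`|`, lapply(per, function(p) p$h$clamped))
    fit <- per[[1]]$fit
    fit$rate <- sum(vapply(per, function(p) p$fit$rate, numeric(1)) * weights) /
      sum(weights)
  }
  list(heights = h, ages = ages, fit = fit)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf(
    "Dated tree: %d internal nodes, rate %.5g %%/MY (%s), %d bootstrap reps\n",
    nrow(x$estimates), x$rate_fit$rate, x$mode, x$bootstrap_reps
  ))
  print(x$estimates)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-node age estimates of a dated tree
#'
#' @param x A `dated_tree` from [date_tree()].
#' @param ... Unused.
#' @return The estimates tibble (one row per internal node).
#' @method tidy dated_tree
#' @export
tidy.dated_tree <- function(x, ...) x$estimates

#' One-row summary of a dated tree
#'
#' @inheritParams tidy.dated_tree
#' @return A tibble with the fitted rate, counts, mode, bootstrap replicate
#'   number and median relative CI.
#' @method glance dated_tree
#' @export
glance.dated_tree <- function(x, ...) {
  tibble::tibble(
    rate = x$rate_fit$rate,
    n_nodes = nrow(x$estimates),
    n_calibrations = nrow(x$rate_fit$calibrations),
    mode = x$mode,
    bootstrap_reps = x$bootstrap_reps,
    median_relative_ci = stats::median(x$estimates$relative_ci)
  )
}

# --- fossil consistency ------------------------------------------------------

#' Check dated node ages against a fossil table
#'
#' A violation is a node whose bootstrap upper bound falls below the minimum
#' age of a fossil attached to it — the estimate rejects a fossil the clade
#' demonstrably possesses. Fossils need not have been used in calibration
#' (held-out fossils are the interesting case).
#'
#' @param x A `dated_tree` from [date_tree()], or a tidy estimates tibble (in
#'   which case `tree` must be supplied).
#' @param fossil_table A calibration-shaped tibble (`clade`, `clade_taxa`,
#'   `min_age`).
#' @param tree Topology used to resolve fossil clades when `x` is a tibble.
#' @return A tibble of violations (possibly empty): `clade`, `min_age`,
#'   `point_age`, `ci_high`.
#' @export
check_fossil_consistency <- function(x, fossil_table, tree = NULL) {
  if (inherits(x, "dated_tree")) {
    tree <- x$tree
    est <- x$estimates
  } else {
    est <- x
    if (is.null(tree)) stop("supply `tree` with a tibble of estimates", call. = FALSE)
  }
  if (is.null(fossil_table) || nrow(fossil_table) == 0) {
    return(tibble::tibble(
      clade = character(), min_age = numeric(),
      point_age = numeric(), ci_high = numeric()
    ))
  }
  rows <- purrr::map_dfr(seq_len(nrow(fossil_table)), function(i) {
    node <- clade_mrca(tree, fossil_table$clade_taxa[i])
    j <- match(node, est$node)
    tibble::tibble(
      clade = fossil_table$clade[i],
      min_age = fossil_table$min_age[i],
      point_age = est$point_age[j],
      ci_high = est$ci_high[j]
    )
  })
  # strict violation beyond numerical tolerance: a binding calibration whose
  # implied age equals its minimum exactly is not a rejection
  rows[rows$ci_high < rows$min_age * (1 - 1e-9), ]
}
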