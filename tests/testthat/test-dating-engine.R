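test_that("node heights equal half the between-clade distances under a clock", {
  tr <- ape::read.tree(text = "((A:2,B:2):3,C:5);")
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 4
  d["A", "C"] <- d["C", "A"] <- 10
  d["B", "C"] <- d["C", "B"] <- 10
  h <- node_heights(tr, d)
  expect_equal(sort(h$height), c(2, 5))
  expect_false(any(h$clamped))
  # identical sequences give zero heights
  z <- d; z[] <- 0
  expect_true(all(node_heights(tr, z)$height == 0))
  expect_error(node_heights(ape::read.tree(text = "((A:1,X:1):1,C:2);"), d),
               "missing")
})

test_that("stylized fixture heights reproduce the model expectation", {
  tr <- make_reference_chronogram()
  d <- stylized_distances(tr)
  h <- node_heights(tr, d)
  old <- clade_mrca(tr, c("Spheniscus_demersus", "Procellaria_aequinoctialis"))
  expect_equal(h$height[h$node == old], 29.4375 / 2) # expected_distance(62)/2
  expect_false(any(h$clamped))
})

test_that("non-monotone heights are clamped to the parent and flagged", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  taxa <- c("A", "B", "C", "D")
  d <- matrix(6, 4, 4, dimnames = list(taxa, taxa))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 10 # child pair deeper than the root pairs
  h <- node_heights(tr, d)
  ab <- h[h$clade_taxa == "A;B", ]
  root <- h[h$clade_taxa == "A;B;C;D", ]
  expect_true(ab$clamped)
  expect_equal(ab$height, root$height)
})

test_that("rate fitting recovers known rates and pooled least squares", {
  tr <- two_depth_tree() # clades at 10 and 60 MY
  d <- stylized_distances(tr)
  h <- node_heights(tr, d)
  cal1 <- tibble::tibble(clade = "ab", clade_taxa = "A;B", min_age = 10,
                         shape = "lognormal", spread = 1)
  fit1 <- calibrate_rate(h, cal1, tr)
  expect_equal(fit1$rate, 1) # unsaturated single calibration recovers r
  cal2 <- dplyr::bind_rows(
    cal1,
    tibble::tibble(clade = "root", clade_taxa = "A;B;C;D", min_age = 60,
                   shape = "lognormal", spread = 1)
  )
  fit2 <- calibrate_rate(h, cal2, tr)
  expect_equal(fit2$rate, (10 * 10 + 60 * 29.375) / 3700) # 0.50338
  expect_equal(fit2$rate, 0.5033784, tolerance = 1e-6)
  # hard_min: the binding calibration pins the rate and no implied age
  # falls below its minimum
  fit3 <- calibrate_rate(h, cal2, tr, mode = "hard_min")
  expect_equal(fit3$rate, min(1, 29.375 / 60))
  expect_true(all(fit3$calibrations$implied_age >= fit3$calibrations$min_age - 1e-9))
  expect_error(calibrate_rate(h, cal1[0, ], tr), "at least one calibration")
})

test_that("uniform priors with huge maxima do not move point_min estimates", {
  tr <- two_depth_tree()
  h <- node_heights(tr, stylized_distances(tr))
  narrow <- tibble::tibble(clade = "ab", clade_taxa = "A;B", min_age = 10,
                           shape = "uniform", spread = 15)
  wide <- narrow; wide$spread <- 1000
  expect_equal(calibrate_rate(h, narrow, tr)$rate,
               calibrate_rate(h, wide, tr)$rate)
})

test_that("soft mode lets ages exceed minima according to the prior", {
  tr <- two_depth_tree()
  h <- node_heights(tr, stylized_distances(tr))
  cals <- tibble::tibble(
    clade = c("ab", "root"), clade_taxa = c("A;B", "A;B;C;D"),
    min_age = c(10, 60), shape = "lognormal", spread = 1
  )
  fit <- calibrate_rate(h, cals, tr, mode = "soft")
  expect_true(all(fit$calibrations$implied_age > fit$calibrations$min_age))
  # widening a uniform prior does move the soft fit
  u <- cals; u$shape <- "uniform"; u$spread <- c(30, 90)
  expect_silent(calibrate_rate(h, u, tr, mode = "soft"))
})

test_that("date_tree collapses intervals without bootstrap and scales with minima", {
  tr <- make_reference_chronogram()
  d <- stylized_distances(tr)
  cals <- default_calibrations()
  dt <- date_tree(tr, d, cals, bootstrap_reps = 0)
  est <- tidy(dt)
  expect_equal(est$ci_low, est$point_age)
  expect_equal(est$ci_high, est$point_age)
  expect_true(all(est$relative_ci == 0))
  expect_s3_class(glance(dt), "tbl_df")
  expect_equal(glance(dt)$n_calibrations, 6)
  # scale equivariance: minima x c -> ages x c
  sc <- cals; sc$min_age <- sc$min_age * 3
  dt3 <- date_tree(tr, d, sc, bootstrap_reps = 0)
  expect_equal(tidy(dt3)$point_age, est$point_age * 3)
  expect_equal(dt3$rate_fit$rate, dt$rate_fit$rate / 3)
  # bootstrap demands alignments
  expect_error(date_tree(tr, d, cals, bootstrap_reps = 10), "bootstrap")
})

test_that("a young unsaturated calibration truncates deep node ages", {
  tr <- make_reference_chronogram()
  d <- stylized_distances(tr) # exact saturation-model distances
  cal <- tibble::tibble(
    clade = "crown_Podicipedidae",
    clade_taxa = "Podiceps_cristatus;Tachybaptus_ruficollis",
    min_age = 9, shape = "lognormal", spread = 1 # true age of the grebe split
  )
  dt <- date_tree(tr, d, cal, bootstrap_reps = 0)
  expect_equal(dt$rate_fit$rate, 1)
  est <- tidy(dt)
  old <- clade_mrca(tr, c("Spheniscus_demersus", "Procellaria_aequinoctialis"))
  expect_equal(est$point_age[est$node == old], 29.4375) # vs 62 MY truth
})

test_that("bootstrap intervals bracket the point estimate and shrink CIs sensibly", {
  tr <- shallow_tree()
  loci <- locus_profiles(ndna_length = 400)[1:2, ]
  set.seed(2)
  alns <- lapply(1:2, function(i) simulate_alignment(tr, loci[i, ]))
  cal <- tibble::tibble(clade = "abcd", clade_taxa = "A;B;C;D", min_age = 12,
                        shape = "lognormal", spread = 1)
  dt <- date_tree(tr, alns, cal, bootstrap_reps = 50, seed = 9)
  est <- tidy(dt)
  expect_true(all(est$ci_low <= est$point_age & est$point_age <= est$ci_high))
  expect_true(all(est$relative_ci >= 0))
  # determinism given the seed
  dt2 <- date_tree(tr, alns, cal, bootstrap_reps = 50, seed = 9)
  expect_identical(tidy(dt), tidy(dt2))
  expect_s3_class(ggplot2::autoplot(dt), "ggplot")
})

test_that("per-locus averaging is available as an alternative combination", {
  tr <- shallow_tree()
  loci <- locus_profiles(ndna_length = 300)[1:2, ]
  set.seed(4)
  alns <- lapply(1:2, function(i) simulate_alignment(tr, loci[i, ]))
  cal <- tibble::tibble(clade = "abcd", clade_taxa = "A;B;C;D", min_age = 12,
                        shape = "lognormal", spread = 1)
  a <- tidy(date_tree(tr, alns, cal, bootstrap_reps = 0))
  b <- tidy(date_tree(tr, alns, cal, bootstrap_reps = 0, combine = "average"))
  expect_equal(dim(a), dim(b))
  expect_false(identical(a$point_age, b$point_age))
})

test_that("fossil-consistency violations are nodes rejected below their minima", {
  tr <- make_reference_chronogram()
  d <- stylized_distances(tr)
  cals <- default_calibrations(include_anhinga = TRUE)
  young <- cals[cals$clade %in% c("crown_Podicipedidae", "crown_Mirandornithes"), ]
  dt <- date_tree(tr, d, young, mode = "hard_min", bootstrap_reps = 0)
  viol <- check_fossil_consistency(dt, cals)
  expect_setequal(viol$clade,
                  c("stem_Sulidae", "stem_Fregatidae", "stem_Spheniscidae"))
  expect_true(all(viol$ci_high < viol$min_age))
  # empty fossil table -> empty violations
  expect_equal(nrow(check_fossil_consistency(dt, cals[0, ])), 0)
})
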