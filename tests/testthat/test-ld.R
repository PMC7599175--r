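test_that("LD octile semantics match the definition on worked cases", {
  # all delayed values in one octile -> the minimum LD 0.125
  expect_equal(compute_ld(c(0, 8, 3.1, 3.2), c(3.1, 3.15, 3.2))$ld, 0.125)
  # delayed at the extremes plus every octile occupied -> LD 1
  expect_equal(compute_ld(0:8, c(0:7 + 0.5, 0, 8))$ld, 1.0)
  # pooled range [0, 8], delayed {0.5, 2.5, 4.5, 6.5} -> 4 of 8 octiles
  p <- compute_ld(0:8, c(0.5, 2.5, 4.5, 6.5))
  expect_equal(p$ld, 0.5)
  expect_equal(which(p$occupied), c(1L, 3L, 5L, 7L))
  expect_equal(p$mask, sum(2L^(c(1, 3, 5, 7) - 1)))
})

test_that("boundary values fall in the right-hand octile; the maximum in octile 8", {
  expect_equal(octile_index(c(0, 1, 4, 7.999, 8), 0, 8), c(1L, 2L, 5L, 8L, 8L))
  p <- compute_ld(c(0, 8), c(8))
  expect_equal(which(p$occupied), 8L)
  expect_equal(compute_ld(c(0, 8), c(1))$occupied[2], TRUE)
})

test_that("degenerate and empty inputs are refused", {
  expect_error(compute_ld(c(2, 2, 2), c(2)), "degenerate")
  expect_error(compute_ld(c(0, 1), numeric(0)), "empty delayed")
  expect_error(compute_ld(c(0, 1), c(2)), "outside")
})

test_that("compute_ld agrees with explicit binning on random instances", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    all_v <- runif(n, -5, 5)
    dv <- sample(all_v, sample(1:n, 1))
    expect_equal(compute_ld(all_v, dv)$ld, brute_force_ld(all_v, dv))
  }
})

test_that("LD is invariant under strictly increasing affine transforms", {
  set.seed(7)
  for (i in 1:100) {
    all_v <- rnorm(20)
    dv <- sample(all_v, 6)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(compute_ld(a * all_v + b, a * dv + b)$ld,
                 compute_ld(all_v, dv)$ld)
  }
})

test_that("adding a delayed value never decreases LD", {
  set.seed(13)
  for (i in 1:100) {
    all_v <- runif(25)
    dv <- sample(all_v, 5)
    extra <- sample(setdiff(all_v, dv), 1)
    expect_gte(compute_ld(all_v, c(dv, extra))$ld, compute_ld(all_v, dv)$ld)
  }
})

test_that("a planted characteristic is ranked first by the selection", {
  planted <- c("mI_Cr.CWMR" = 3L)
  tab <- generate_cohort(cohort_spec(103, 0.126, planted_localised = planted,
                                     dropout_rate = 0, seed = 2),
                         default_class_distribution("motor"))
  # oracle: brute-force LD of all 42 characteristics, verify the argmin
  lds <- vapply(cohort_characteristics(tab), function(id)
    brute_force_ld(tab[[id]], tab[[id]][tab$label == 1L]), 0)
  expect_equal(names(which.min(lds)), "mI_Cr.CWMR")
  sel <- suppressWarnings(select_characteristics(tab, ld_threshold = 0.25))
  expect_equal(sel$selected[1], "mI_Cr.CWMR")
  expect_equal(sel$profiles$ld[sel$profiles$characteristic == "mI_Cr.CWMR"],
               0.125)
})

test_that("a vacuous threshold selects every non-degenerate characteristic", {
  tab <- generate_cohort(cohort_spec(50, 0.2, dropout_rate = 0, seed = 3),
                         default_class_distribution("motor"))
  sel <- select_characteristics(tab, ld_threshold = 1.0, inner_size = 5)
  expect_setequal(sel$selected, cohort_characteristics(tab))
  expect_length(sel$inner_subset, 5L)
})

test_that("the motor-style configuration yields an inner subset of 5 from 7+", {
  planted <- structure(rep(c(3L, 4L, 5L), length.out = 7),
                       names = c("NAA_Cho.CWMR", "NAA_mI.CWMR", "mI_Cr.CWMR",
                                 "mI_Cr.CWML", "NAA_Cho.PWMR", "Cho_Cr.PWMR",
                                 "NAA_Cr.PWML"))
  tab <- generate_cohort(cohort_spec(103, 0.126, planted_localised = planted,
                                     dropout_rate = 0, seed = 5),
                         default_class_distribution("motor"))
  sel <- select_characteristics(tab, ld_threshold = 0.375, inner_size = 5)
  expect_true(all(names(planted) %in% sel$selected))
  expect_length(sel$inner_subset, 5L)
  expect_true(all(sel$inner_subset %in% sel$selected))
  # the inner subset is the strongest-localisation (lowest-LD) prefix
  expect_identical(sel$inner_subset, head(sel$selected, 5))
})

test_that("ties are broken by occupied-octile span, then name", {
  # two characteristics with LD 0.25: one with adjacent octiles (span 2/8),
  # one with spread octiles (span 5/8); the compact one ranks first
  n <- 20
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    label = c(rep(1L, 4), rep(0L, n - 4)),
                    severe_injury = 0L)
  tab$FA.FWMR <- c(1.1, 1.15, 2.1, 2.15, seq(0, 8, length.out = n - 4)) / 10
  tab$FA.FWML <- c(1.1, 1.15, 5.1, 5.15, seq(0, 8, length.out = n - 4)) / 10
  class(tab) <- c("cohort_table", "data.frame")
  sel <- select_characteristics(tab, ld_threshold = 1, inner_size = 1,
                                min_delayed = 3)
  prof <- sel$profiles
  expect_equal(prof$ld[prof$characteristic == "FA.FWMR"],
               prof$ld[prof$characteristic == "FA.FWML"])
  expect_equal(sel$selected[1], "FA.FWMR")
})

test_that("missing values use pairwise deletion and min_delayed gates profiling", {
  tab <- generate_cohort(cohort_spec(60, 0.2, dropout_rate = 0, seed = 11),
                         default_class_distribution("motor"))
  # knock out most delayed values of one characteristic
  del <- which(tab$label == 1L)
  tab$NAA_Cho.FWMR[del[-(1:2)]] <- NA
  sel <- select_characteristics(tab, ld_threshold = 1, min_delayed = 3)
  prof <- sel$profiles
  expect_true(is.na(prof$ld[prof$characteristic == "NAA_Cho.FWMR"]))
  expect_false("NAA_Cho.FWMR" %in% sel$selected)
  # a characteristic with some missing values is still profiled on the rest
  tab2 <- tab
  tab2$NAA_Cr.FWMR[1:5] <- NA
  sel2 <- select_characteristics(tab2, ld_threshold = 1)
  p2 <- sel2$profiles
  expect_false(is.na(p2$ld[p2$characteristic == "NAA_Cr.FWMR"]))
})

test_that("empty selection warns rather than errors", {
  tab <- generate_cohort(cohort_spec(103, 0.3, dropout_rate = 0, seed = 19),
                         default_class_distribution("motor"))
  expect_warning(sel <- select_characteristics(tab, ld_threshold = 0.125),
                 "empty")
  expect_length(sel$selected, 0L)
})
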