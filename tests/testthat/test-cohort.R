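motor_dist <- default_class_distribution("motor")

test_that("labels are Bernoulli at the requested prevalence", {
  # the motor study conditions: 103 infants at 12.6% delay prevalence
  counts <- vapply(1:50, function(s) {
    tab <- generate_cohort(cohort_spec(103, 0.126, seed = s,
                                       dropout_rate = 0), motor_dist)
    sum(tab$label)
  }, 0L)
  expected <- 103 * 0.126  # 12.978, i.e. 13 delayed in expectation
  se <- sqrt(103 * 0.126 * 0.874 / 50)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("no dropout and no planting give a complete, finite table", {
  tab <- generate_cohort(cohort_spec(60, 0.2, dropout_rate = 0, seed = 3),
                         motor_dist)
  vals <- as.matrix(tab[, cohort_characteristics(tab)])
  expect_true(all(is.finite(vals)))
  expect_false(any(is_incomplete(tab)))
  expect_true(all(tab$label %in% 0:1))
  fa <- grep("^FA\\.", names(tab), value = TRUE)
  expect_true(all(vals[, fa] >= 0 & vals[, fa] <= 1))
  md <- grep("^MD\\.", names(tab), value = TRUE)
  expect_true(all(vals[, md] > 0))
})

test_that("planted characteristics have LD 0.125 on the delayed subgroup", {
  # binning oracle: recompute occupied octiles of the pooled range directly
  planted <- c("mI_Cr.CWMR" = 3L, "FA.FWMR" = 6L)
  for (s in 1:5) {
    tab <- generate_cohort(cohort_spec(103, 0.126, planted_localised = planted,
                                       dropout_rate = 0, seed = s), motor_dist)
    for (id in names(planted)) {
      v <- tab[[id]]
      expect_equal(brute_force_ld(v, v[tab$label == 1L]), 0.125)
      expect_equal(compute_ld(v, v[tab$label == 1L])$ld, 0.125)
    }
  }
})

test_that("dropout erases metabolite values at the requested rate, never DTI", {
  tab <- generate_cohort(cohort_spec(400, 0.1, dropout_rate = 0.05, seed = 9),
                         motor_dist)
  grid <- characteristic_grid()
  mrs <- grid$characteristic[!grid$measure %in% c("MD", "FA")]
  dti <- grid$characteristic[grid$measure %in% c("MD", "FA")]
  n_na <- sum(is.na(tab[, mrs]))
  n_cells <- 400 * length(mrs)
  se <- sqrt(n_cells * 0.05 * 0.95)
  expect_lt(abs(n_na - n_cells * 0.05), 4 * se)
  expect_equal(sum(is.na(tab[, dti])), 0L)
  expect_equal(is_incomplete(tab), rowSums(is.na(tab[, mrs])) > 0)
})

test_that("empirical class means converge to the distribution means", {
  tab <- generate_cohort(cohort_spec(4000, 0.5, dropout_rate = 0, seed = 21),
                         motor_dist)
  for (cls in 0:1) {
    sub <- tab[tab$label == cls, ]
    mu <- if (cls == 1) motor_dist$mean_delayed else motor_dist$mean_normal
    sd <- if (cls == 1) motor_dist$sd_delayed else motor_dist$sd_normal
    z <- abs(colMeans(sub[, motor_dist$characteristic]) - mu) /
      (sd / sqrt(nrow(sub)))
    # 42 simultaneous comparisons per class: nearly all inside 3 SEs of the
    # mean, every one inside a family-wise 4.5-SE band
    expect_gte(mean(z < 3), 0.95)
    expect_lt(max(z), 4.5)
  }
})

test_that("within-region equicorrelation is reflected in the draws", {
  d <- as_class_distribution(default_class_distribution("motor"), rho = 0.6)
  tab <- generate_cohort(cohort_spec(2000, 0.5, dropout_rate = 0, seed = 4), d)
  same_region <- cor(tab$NAA_Cho.CWMR, tab$NAA_Cr.CWMR)
  other_region <- cor(tab$NAA_Cho.CWMR, tab$NAA_Cr.PWML)
  expect_gt(same_region, 0.4)
  expect_lt(abs(other_region), 0.15)
})

test_that("identical spec and seed give a byte-identical CSV", {
  spec <- cohort_spec(50, 0.2, planted_localised = c("FA.FWMR" = 4L),
                      seed = 77)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec, motor_dist), f1)
  write_cohort(generate_cohort(spec, motor_dist), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("write/read round trip is value-exact including missing cells", {
  tab <- generate_cohort(cohort_spec(40, 0.25, dropout_rate = 0.05, seed = 5),
                         motor_dist)
  f <- tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f)
  expect_identical(back$subject_id, tab$subject_id)
  expect_identical(back$label, tab$label)
  for (id in cohort_characteristics(tab))
    expect_identical(back[[id]], tab[[id]])
})

test_that("malformed cohort files are rejected with informative messages", {
  tab <- generate_cohort(cohort_spec(10, 0.3, dropout_rate = 0, seed = 1),
                         motor_dist)
  f <- tempfile(fileext = ".csv")

  write_cohort(tab, f)
  lines <- readLines(f)
  lines[1] <- sub("FA.FWMR", "FA.XXXX", lines[1], fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_cohort(f), "XXXX")

  write_cohort(tab, f)
  lines <- readLines(f)
  lines[2] <- sub("^(S[0-9]+,)[01]", "\\12", lines[2])  # label -> 2
  writeLines(lines, f)
  expect_error(read_cohort(f), "label")

  write_cohort(tab, f)
  lines <- readLines(f)
  parts <- strsplit(lines[3], ",")[[1]]
  parts[5] <- "not_a_number"
  lines[3] <- paste(parts, collapse = ",")
  writeLines(lines, f)
  expect_error(read_cohort(f), "row 2")
})

test_that("impossible or inconsistent specs are refused", {
  expect_error(cohort_spec(5, 0.1), "below 1")
  expect_error(cohort_spec(100, 0.2, planted_localised = c("FA.FWMR" = 9L)),
               "octile")
  expect_error(cohort_spec(100, 0.2,
                           planted_localised = c("FA.YYYY" = 3L)), "region")
  d <- motor_dist[motor_dist$characteristic != "FA.FWMR", ]
  expect_error(generate_cohort(cohort_spec(50, 0.2, seed = 1), d), "FA.FWMR")
})
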