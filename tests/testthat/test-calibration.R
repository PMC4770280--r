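test_that("goodness of fit matches the closed-form coefficient of determination", {
  obs <- c(1e4, 1e5, 1e6, 1e7)          # realistic cells/kg magnitudes
  expect_equal(goodness_of_fit(obs, obs), 1)
  # constant multiplicative offset is a shift on the log scale: still R^2 = 1
  # (up to the +1 cells/kg regularising offset, negligible at these scales)
  expect_equal(goodness_of_fit(2 * obs, obs), 1, tolerance = 1e-8)

  # hand-computable 4-point example on the raw scale: for simple linear
  # regression R^2 is the squared Pearson correlation
  pred <- c(1.2, 1.9, 3.3, 3.8)
  o <- c(1, 2, 3, 4)
  expect_equal(goodness_of_fit(pred, o, log10_scale = FALSE),
               stats::cor(pred, o)^2)

  expect_error(goodness_of_fit(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(goodness_of_fit(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("dataset validation and CSV round trip", {
  d <- generate_dataset(mouse_phys, table1, iv_mouse,
                        noise = noise_model(cv = 0.25, n_animals = 5, seed = 3))
  expect_s3_class(d, "biodistribution_dataset")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_biodistribution_csv(d, tmp)
  back <- read_biodistribution_csv(tmp, species = "mouse")
  expect_equal(back$conc_cells_per_kg, d$conc_cells_per_kg)
  expect_equal(back$compartment, d$compartment)

  bad <- as.data.frame(d)
  bad$compartment[1] <- "brain"
  expect_error(biodistribution_dataset(bad), "unknown compartment")
  bad2 <- as.data.frame(d)
  bad2$conc_cells_per_kg[1] <- -1
  expect_error(biodistribution_dataset(bad2), "non-negative")
})

test_that("noiseless self-consistency: truth as init stays at truth", {
  d <- generate_dataset(mouse_phys, table1, iv_mouse,
                        noise = noise_model(cv = 0))
  fit <- fit_parameters(d, mouse_phys, init = table1, dose_events = iv_mouse,
                        free = lung_block, n_starts = 1)
  expect_lt(fit$objective, 1e-12)
  expect_equal(params_to_vector(fit$params)[lung_block],
               params_to_vector(table1)[lung_block], tolerance = 1e-6)
  expect_true(fit$convergence$converged)
  expect_gt(fit$r2, 0.999)
})

test_that("noiseless recovery from a perturbed start is within 5%", {
  d <- generate_dataset(mouse_phys, table1, iv_mouse,
                        noise = noise_model(cv = 0))
  v0 <- params_to_vector(table1)
  v0[lung_block] <- v0[lung_block] * 1.5
  fit <- fit_parameters(d, mouse_phys, init = vector_to_params(v0),
                        dose_events = iv_mouse, free = lung_block,
                        n_starts = 1)
  est <- params_to_vector(fit$params)[lung_block]
  truth <- params_to_vector(table1)[lung_block]
  expect_lt(max(abs(est - truth) / truth), 0.05)
})

test_that("refitting from the returned estimate is a fixed point", {
  # noiseless data give a sharp, exactly attainable minimum, where the
  # fixed-point contract is well defined
  d <- generate_dataset(mouse_phys, table1, iv_mouse,
                        noise = noise_model(cv = 0))
  free2 <- c("lung.partition", "lung.k_arrest")
  v0 <- params_to_vector(table1)
  v0[free2] <- v0[free2] * 1.3
  f1 <- fit_parameters(d, mouse_phys, init = vector_to_params(v0),
                       dose_events = iv_mouse, free = free2, n_starts = 1)
  f2 <- fit_parameters(d, mouse_phys, init = f1$params,
                       dose_events = iv_mouse, free = free2, n_starts = 1)
  v1 <- params_to_vector(f1$params)[free2]
  v2 <- params_to_vector(f2$params)[free2]
  expect_lt(max(abs(v2 - v1) / v1), 1e-8)
  expect_lte(f2$objective, f1$objective + 1e-12)
})

test_that("disease-mode refit recovers the direction of the generating change", {
  mi_truth <- generate_disease_variant(table1, "heart",
                                       arrest_multiplier = 2,
                                       depletion_multiplier = 0.5)
  d <- generate_dataset(mouse_phys, mi_truth, iv_mouse,
                        noise = noise_model(cv = 0))
  heart_free <- c("heart.k_arrest", "heart.k_depletion")
  fit <- fit_parameters(d, mouse_phys, init = table1, dose_events = iv_mouse,
                        free = heart_free, n_starts = 1)
  est <- params_to_vector(fit$params)
  base <- params_to_vector(table1)
  expect_gt(est[["heart.k_arrest"]], base[["heart.k_arrest"]])
  expect_lt(est[["heart.k_depletion"]], base[["heart.k_depletion"]])
  # fixed parameters really were held fixed
  held <- setdiff(names(base), heart_free)
  expect_equal(est[held], base[held])
})

test_that("fit input validation", {
  d <- generate_dataset(mouse_phys, table1, iv_mouse,
                        noise = noise_model(cv = 0))
  expect_error(fit_parameters(d, mouse_phys, init = table1,
                              dose_events = iv_mouse, free = "lung.k_typo"),
               "unknown free parameter")
  v0 <- params_to_vector(table1)
  v0["lung.partition"] <- 5e4                 # above the default upper bound
  expect_error(fit_parameters(d, mouse_phys, init = vector_to_params(v0),
                              dose_events = iv_mouse, free = lung_block),
               "outside bounds")
})
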