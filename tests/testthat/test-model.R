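test_that("partition-limited venous outflow concentration", {
  expect_equal(venous_outflow_concentration(100, 1), 100)
  expect_equal(venous_outflow_concentration(0, 1633.24), 0)
  expect_equal(venous_outflow_concentration(742.733, 742.733), 1)
  expect_error(venous_outflow_concentration(10, 0), "positive")
  expect_error(venous_outflow_concentration(10, -2), "positive")
})

test_that("state derivative vanishes on the empty system and at pure-circulation equilibrium", {
  zero <- stats::setNames(numeric(15), mscpbk:::state_names())
  expect_equal(state_derivative(zero, table1, mouse_phys), zero)

  # all rates off, P = 1 everywhere, spatially uniform concentration
  v <- params_to_vector(table1)
  v[] <- 0
  v[grepl("partition", names(v))] <- 1
  inert <- vector_to_params(v)
  uni <- zero
  uni[grepl("^C_", names(uni))] <- 1234
  d <- state_derivative(uni, inert, mouse_phys)
  # residual is pure floating-point cancellation of O(Q/V * C) fluxes
  expect_lt(max(abs(d)), 1e-6)
})

test_that("derivative conserves total cells at a random positive state", {
  set.seed(42)
  phys <- mouse_phys
  org <- phys$organs[match(PBK_ORGANS, phys$organs$name), ]
  for (rep in 1:5) {
    st <- stats::setNames(stats::runif(15, 0, 1e6), mscpbk:::state_names())
    d <- state_derivative(st, table1, phys)
    # independent mass weights: concentrations x volumes + amounts
    total_rate <- d[["C_arterial"]] * phys$arterial_blood_volume +
      d[["C_venous"]] * phys$venous_blood_volume +
      sum(d[paste0("C_", PBK_ORGANS)] * org$vascular_volume) +
      sum(d[paste0("A_", PBK_ORGANS)]) + d[["D_cum"]]
    scale <- sum(abs(d))
    expect_lt(abs(total_rate) / scale, 1e-9)
  }
})

test_that("zero dose gives an identically zero trajectory", {
  sim <- simulate_pbk(mouse_phys, table1, dose_event("intravenous", 0), grid24)
  expect_equal(max(abs(sim$states)), 0)
  expect_equal(survival_fraction(sim, 12), 1)
})

test_that("the system is first-order: outputs scale exactly with dose", {
  s1 <- simulate_pbk(mouse_phys, table1, dose_event("intravenous", 5e5),
                     grid24, rtol = 1e-10, atol = 1e-8)
  s2 <- simulate_pbk(mouse_phys, table1, dose_event("intravenous", 1e6),
                     grid24, rtol = 1e-10, atol = 1e-8)
  rel <- abs(s2$states - 2 * s1$states) /
    pmax(abs(2 * s1$states), 1e-8 * max(s1$states))
  expect_lt(max(rel), 1e-8)
})

test_that("simulated trajectories conserve cells and stay non-negative", {
  bal <- total_cell_balance(sim_mouse_iv)
  expect_lt(max(abs(bal - 5e5)) / 5e5, 1e-6)
  # independent accounting from the raw states
  expect_lt(max(abs(manual_total_cells(sim_mouse_iv) - 5e5)) / 5e5, 1e-6)
  floor_conc <- -1e-9 * 5e5 / (mouse_phys$arterial_blood_volume +
                                 mouse_phys$venous_blood_volume)
  expect_gt(min(sim_mouse_iv$states), floor_conc)
})

test_that("survival fraction semantics", {
  expect_equal(survival_fraction(sim_mouse_iv, 0), 1)
  v <- params_to_vector(table1)
  v[grepl("k_depletion", names(v))] <- 0
  nodep <- vector_to_params(v)
  sim <- simulate_pbk(mouse_phys, nodep, iv_mouse, grid24)
  expect_equal(survival_fraction(sim, c(1, 12, 24)), rep(1, 3),
               tolerance = 1e-8)
  expect_error(survival_fraction(sim_mouse_iv, 25), "range")
})

test_that("compartment amounts sum to the dose with the depletion ledger", {
  tt <- c(0.1, 1, 10, 24)
  total <- rowSums(vapply(c(PBK_ORGANS, "arterial_blood", "venous_blood"),
                          function(o) amount_in_organ(sim_mouse_iv, o, tt),
                          numeric(length(tt))))
  dcum <- 5e5 * (1 - survival_fraction(sim_mouse_iv, tt))
  expect_equal(total + dcum, rep(5e5, length(tt)), tolerance = 1e-6)
  expect_error(amount_in_organ(sim_mouse_iv, "brain", 1), "unknown organ")
})

test_that("tidy export is consistent with the accessor functions", {
  df <- as.data.frame(sim_mouse_iv)
  expect_named(df, c("time_h", "compartment", "amount_cells",
                     "concentration_cells_per_L", "concentration_cells_per_kg",
                     "arrested_cells"))
  sub <- df[df$compartment == "liver" & df$time_h == 3, ]
  expect_equal(sub$amount_cells, amount_in_organ(sim_mouse_iv, "liver", 3))
  expect_equal(sub$concentration_cells_per_kg,
               concentration_per_kg(sim_mouse_iv, "liver", 3))
  subb <- df[df$compartment == "venous_blood" & df$time_h == 3, ]
  expect_equal(subb$concentration_cells_per_kg,
               concentration_per_kg(sim_mouse_iv, "blood", 3))
})

test_that("invalid grids and tolerances are rejected", {
  expect_error(simulate_pbk(mouse_phys, table1, iv_mouse, c(0, 0, 1)),
               "strictly increasing")
  expect_error(simulate_pbk(mouse_phys, table1, dose_event("intravenous", 1, time = -1),
                            c(0, 1)), "first dose")
  expect_error(simulate_pbk(mouse_phys, table1, iv_mouse, c(0, 1), rtol = 0),
               "positive")
})
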