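test_that("bundled physiologies load, validate, and close the circulatory loop", {
  for (sp in c("mouse", "rat", "human")) {
    phys <- load_species_physiology(sp)
    expect_s3_class(phys, "species_physiology")
    expect_setequal(phys$organs$name, PBK_ORGANS)

    # independent summation straight from the raw YAML file
    raw <- yaml::read_yaml(system.file("extdata", "physiology",
                                       paste0(sp, ".yaml"), package = "mscpbk"))
    syst <- setdiff(PBK_ORGANS, "lung")
    q_sum <- sum(vapply(raw$organs[syst],
                        function(o) o$blood_flow_L_per_h, 0))
    co <- raw$cardiac_output_L_per_h
    expect_lt(abs(q_sum - co), 0.01 * co)
    expect_equal(raw$organs$lung$blood_flow_L_per_h, co)

    # volumes close under body weight at 1 kg/L
    vol <- raw$arterial_blood_volume_L + raw$venous_blood_volume_L +
      sum(vapply(raw$organs, function(o) o$total_volume_L, 0))
    expect_lte(vol, raw$body_weight_kg * (1 + 1e-9))
  }
})

test_that("unknown species and invalid configs are rejected", {
  expect_error(load_species_physiology("unicorn"), "unknown species")

  # config with vascular_volume > total_volume
  bad <- mouse_phys
  bad$organs$vascular_volume[bad$organs$name == "liver"] <-
    2 * bad$organs$total_volume[bad$organs$name == "liver"]
  expect_error(validate_species_physiology(bad), "vascular_volume")
})

test_that("validation rejects every single-field corruption", {
  for (field in c("body_weight", "arterial_blood_volume",
                  "venous_blood_volume", "cardiac_output")) {
    for (val in c(-1, 0, NA_real_)) {
      bad <- mouse_phys
      bad[[field]] <- val
      expect_error(validate_species_physiology(bad), field)
    }
  }
  for (col in c("total_volume", "vascular_volume", "blood_flow")) {
    for (i in seq_along(PBK_ORGANS)) {
      bad <- mouse_phys
      bad$organs[[col]][i] <- -abs(bad$organs[[col]][i])
      expect_error(validate_species_physiology(bad))
    }
  }
  # missing organ
  bad <- mouse_phys
  bad$organs <- bad$organs[bad$organs$name != "spleen", ]
  expect_error(validate_species_physiology(bad), "organ set")
  # flow sum broken
  bad <- mouse_phys
  bad$organs$blood_flow[bad$organs$name == "kidney"] <-
    bad$organs$blood_flow[bad$organs$name == "kidney"] * 3
  expect_error(validate_species_physiology(bad), "cardiac")
})

test_that("write/read round trip reproduces every field bit-exactly", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_species_physiology(mouse_phys, tmp)
  back <- load_species_physiology(tmp)
  expect_identical(back$body_weight, mouse_phys$body_weight)
  expect_identical(back$cardiac_output, mouse_phys$cardiac_output)
  expect_identical(back$arterial_blood_volume, mouse_phys$arterial_blood_volume)
  expect_identical(back$venous_blood_volume, mouse_phys$venous_blood_volume)
  ord <- match(mouse_phys$organs$name, back$organs$name)
  for (col in c("total_volume", "vascular_volume", "blood_flow")) {
    expect_identical(back$organs[[col]][ord], mouse_phys$organs[[col]])
  }
})

test_that("allometric rescaling: identity, volume proportionality, flow exponent", {
  same <- scale_physiology(mouse_phys, mouse_phys$body_weight)
  expect_equal(same$organs$total_volume, mouse_phys$organs$total_volume)
  expect_equal(same$cardiac_output, mouse_phys$cardiac_output)

  twice <- scale_physiology(mouse_phys, 2 * mouse_phys$body_weight)
  expect_equal(twice$organs$total_volume, 2 * mouse_phys$organs$total_volume)
  expect_equal(twice$organs$vascular_volume, 2 * mouse_phys$organs$vascular_volume)
  expect_equal(twice$organs$blood_flow,
               2^0.75 * mouse_phys$organs$blood_flow)
  expect_equal(twice$cardiac_output, 2^0.75 * mouse_phys$cardiac_output)

  expect_error(scale_physiology(mouse_phys, -1), "positive")
})
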