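desk_study_a_cfg <- function(seed = 1) {
  study_a_config(sim_params = fix_params32,
                 streak_train = train_config(epochs = 2, seed = seed),
                 imputation_train = train_config(epochs = 2, seed = seed),
                 n_test_patients = 1L, seed = seed)
}

test_that("the synthetic-data study runs the two-model cascade faithfully", {
  cohort <- make_cohort(3, 2, fix_spec32, seed = 4)
  res <- run_study_a(cohort, desk_study_a_cfg())
  expect_s3_class(res$streak_model, "pix2pix")
  expect_s3_class(res$imputation_model, "pix2pix")
  expect_identical(res$manifest$n_train_pairs, 4L)
  expect_length(res$manifest$test_patients, 1)

  # cascade contract: the imputation model's training inputs are the
  # streak model's outputs on the same slices, byte for byte
  for (i in seq_along(res$data$imputation_pairs)) {
    expect_identical(res$data$imputation_pairs[[i]]$input_img,
                     res$data$streak_outputs[[i]])
  }
  # streak targets are FOV-masked (zero exterior); imputation targets are
  # the full anatomy
  for (i in seq_along(res$data$sim_pairs)) {
    p <- res$data$sim_pairs[[i]]
    expect_true(any(res$data$streak_pairs[[i]]$target_img == 0))
    expect_identical(res$data$imputation_pairs[[i]]$target_img, p$full_gt)
  }
  # data hygiene: no held-out slice fingerprint appears in training
  expect_length(intersect(res$manifest$train_fingerprints,
                          res$manifest$test_fingerprints), 0)
  # seeded rerun reproduces the manifest exactly
  res2 <- run_study_a(cohort, desk_study_a_cfg())
  expect_identical(res$manifest, res2$manifest)
})

test_that("the clinical-style base training guards against patient leakage", {
  cohort <- make_cohort(2, 2, fix_spec32, seed = 6)
  patients <- lapply(cohort, function(v) {
    list(ct = v,
         cbcts = list(simulate_scbct_volume(v, fix_params32, seed = 3)$cbct))
  })
  cfg <- study_b_config(base_train = train_config(epochs = 1, seed = 1),
                        transfer = transfer_config(epochs = 1, seed = 1),
                        n_base_patients = 2L,
                        transfer_patient_id = "P001",
                        prep = list(register = FALSE), seed = 1)
  expect_error(run_study_b_base(patients, cfg), "excluded")

  cfg$transfer_patient_id <- "P999"
  res <- run_study_b_base(patients, cfg)
  expect_s3_class(res$base_model, "pix2pix")
  expect_identical(res$manifest$n_train_pairs, 4L)
  expect_identical(res$manifest$cohort, c("P001", "P002"))
})

test_that("patient-specific models use the requested CBCT sets and spare the base", {
  vol <- make_cohort(1, 3, fix_spec32, seed = 7)[[1]]
  sets <- lapply(1:2, function(k)
    simulate_scbct_volume(vol, fix_params32, seed = 10 + k)$cbct)
  patient <- list(ct = vol, cbcts = sets)
  base <- pix2pix(sim_full_pairs(vol, fix_params32, seed = 5),
                  config = train_config(epochs = 1, seed = 1))
  cs <- layer_checksums(base)
  cfg <- study_b_config(transfer = transfer_config(epochs = 1, seed = 2),
                        prep = list(register = FALSE), seed = 2)
  ps1 <- make_patient_specific(base, patient, 1L, cfg)
  ps2 <- make_patient_specific(base, patient, 2L, cfg)
  expect_identical(ps1$label, "Patient-specific model 1")
  expect_identical(ps2$label, "Patient-specific model 2")
  expect_identical(layer_checksums(base), cs)
  expect_error(make_patient_specific(base, patient, 3L, cfg), "exceeds")
})

test_that("volume inference preserves slice count, order, thickness and range", {
  vol <- make_cohort(1, 3, fix_spec32, seed = 8)[[1]]
  sim <- simulate_scbct_volume(vol, fix_params32, seed = 2)
  m <- pix2pix(sim_full_pairs(vol, fix_params32, seed = 2),
               config = train_config(epochs = 1, seed = 1))
  out <- infer_volume(m, sim$cbct)
  expect_identical(n_slices(out), 3L)
  expect_identical(out$slice_thickness, vol$slice_thickness)
  expect_gte(min(unlist(out$slices)), -1024)
  expect_lte(max(unlist(out$slices)), 3071)
  expect_identical(out$slices[[2]], predict(m, sim$cbct$slices[[2]]))
  expect_identical(infer_volume(m, sim$cbct)$slices, out$slices)
})
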