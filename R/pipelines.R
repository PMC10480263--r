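#' Configuration for the synthetic-data study (two-model cascade)
#'
#' Study plan: simulate streaked, FOV-truncated CBCT slices from CT;
#' train a streak-removal model on (simulated CBCT -> FOV-masked clean
#' CT); then train an anatomy-imputation model whose inputs are the
#' streak model's own outputs and whose targets are the full CT.
#'
#' @param sim_params a [sim_params()].
#' @param streak_train,imputation_train [train_config()]s (200 epochs
#'   each at study scale).
#' @param n_test_patients patients held out (by seeded draw) for testing.
#' @param seed global seed.
#' @return list of class `study_a_config`.
#' @export
study_a_config <- function(sim_params = cbctrepair::sim_params(),
                           streak_train = train_config(epochs = 200),
                           imputation_train = train_config(epochs = 200),
                           n_test_patients = 1L, seed = 1L) {
  if (n_test_patients < 1) stop("'n_test_patients' must be >= 1")
  structure(as.list(environment()), class = "study_a_config")
}

#' Configuration for the clinical-style study (base + transfer)
#'
#' @param base_train [train_config()] for the multi-patient base model
#'   (500 epochs at study scale).
#' @param transfer [transfer_config()] for patient-specific refinement.
#' @param n_base_patients patients in the base cohort (15 at study
#'   scale).
#' @param transfer_patient_id patient reserved for transfer learning and
#'   testing; must not appear in the base cohort.
#' @param prep list passed to [build_training_pairs()] (`register`,
#'   `target_size`, `couch_row`, ...).
#' @param seed global seed.
#' @return list of class `study_b_config`.
#' @export
study_b_config <- function(base_train = train_config(epochs = 500),
                           transfer = transfer_config(epochs = 500),
                           n_base_patients = 15L,
                           transfer_patient_id = NULL,
                           prep = list(), seed = 1L) {
  structure(as.list(environment()), class = "study_b_config")
}

pair_from_sim <- function(input, target, patient_id, slice_index, tag) {
  structure(list(input_img = input, target_img = target,
                 patient_id = patient_id, slice_index = slice_index,
                 stage_tag = tag),
            class = "paired_sample")
}

#' Run the synthetic-data study end to end
#'
#' Simulates CBCT pairs for the training patients, trains the
#' streak-removal model on (simulated CBCT -> FOV-masked CT), feeds that
#' model's outputs forward as the imputation model's inputs, and trains
#' the imputation model against the full CT. The two models are trained
#' sequentially, exactly mirroring the cascade. A manifest records
#' seeds, the patient split, pair counts and data fingerprints.
#'
#' @param ct_dataset list of [ct_volume()] objects.
#' @param config a [study_a_config()].
#' @return list with `streak_model`, `imputation_model`, `manifest`, and
#'   `data` (the generated training/testing material).
#' @export
run_study_a <- function(ct_dataset, config = study_a_config()) {
  if (!length(ct_dataset)) stop("'ct_dataset' must be nonempty")
  ids <- vapply(ct_dataset, `[[`, "", "patient_id")
  set.seed(derive_seed(config$seed, "split"))
  test_ids <- if (length(ct_dataset) > config$n_test_patients)
    sample(ids, config$n_test_patients) else character(0)
  train_vols <- ct_dataset[!ids %in% test_ids]
  test_vols <- ct_dataset[ids %in% test_ids]

  sim_one <- function(vol, offset) {
    lapply(seq_along(vol$slices), function(i)
      simulate_scbct_slice(vol$slices[[i]], config$sim_params,
                           seed = derive_seed(config$seed, "simulate",
                                              offset + i)))
  }
  flat <- list(); flat_pid <- character(0); off <- 0L
  for (v in train_vols) {
    s <- sim_one(v, off)
    flat <- c(flat, s)
    flat_pid <- c(flat_pid, rep(v$patient_id, length(s)))
    off <- off + 1000L
  }
  streak_pairs <- lapply(seq_along(flat), function(i)
    pair_from_sim(flat[[i]]$scbct, flat[[i]]$streak_gt,
                  flat_pid[i], i, "streak"))
  streak_model <- pix2pix(streak_pairs, config = config$streak_train,
                          label = "streak-removal model")

  streak_outputs <- lapply(flat, function(p)
    infer_slice(streak_model, p$scbct))
  imputation_pairs <- lapply(seq_along(flat), function(i)
    pair_from_sim(streak_outputs[[i]], flat[[i]]$full_gt,
                  flat_pid[i], i, "imputation"))
  imputation_model <- pix2pix(imputation_pairs,
                              config = config$imputation_train,
                              label = "image imputation model")

  manifest <- list(
    seed = config$seed,
    train_patients = setdiff(ids, test_ids),
    test_patients = test_ids,
    n_train_pairs = length(flat),
    replaced_fractions = vapply(flat, `[[`, 0, "replaced_fraction"),
    train_fingerprints = vapply(streak_pairs, function(p)
      fingerprint(p$input_img), character(1)),
    test_fingerprints = vapply(
      unlist(lapply(test_vols, `[[`, "slices"), recursive = FALSE),
      fingerprint, character(1))
  )
  list(streak_model = streak_model, imputation_model = imputation_model,
       manifest = manifest,
       data = list(sim_pairs = flat, streak_pairs = streak_pairs,
                   streak_outputs = streak_outputs,
                   imputation_pairs = imputation_pairs,
                   test_volumes = test_vols))
}

#' Train the clinical-style base model
#'
#' Builds preprocessed training pairs for the base cohort only (the
#' transfer patient must be excluded) and trains a single model that
#' both removes artifacts and imputes missing anatomy.
#'
#' @param patients list of `list(ct = ct_volume, cbcts = list of
#'   ct_volume)` entries.
#' @param config a [study_b_config()].
#' @return list with `base_model` and `manifest`.
#' @export
run_study_b_base <- function(patients, config = study_b_config()) {
  ids <- vapply(patients, function(p) p$ct$patient_id, "")
  if (!is.null(config$transfer_patient_id) &&
      config$transfer_patient_id %in% ids)
    stop("transfer patient '", config$transfer_patient_id,
         "' must be excluded from the base training cohort")
  pairs <- list()
  for (p in patients)
    pairs <- c(pairs, build_training_pairs(p$ct, p$cbcts, config$prep))
  cfg <- config$base_train
  cfg$seed <- derive_seed(config$seed, "train", 1L)
  base_model <- pix2pix(pairs, config = cfg, label = "base clinical model")
  manifest <- list(
    seed = config$seed,
    cohort = ids,
    n_train_pairs = length(pairs),
    pair_fingerprints = vapply(pairs, function(p)
      fingerprint(p$input_img), character(1))
  )
  list(base_model = base_model, manifest = manifest)
}

#' Produce a patient-specific model by transfer learning
#'
#' Builds pairs from the patient's planning CT and their first
#' `n_cbct_sets` setup CBCT sets (one set: 49 pairs at clinical scale;
#' two sets double that to 98) and retrains only the final generator
#' layers of the base model. The base model is returned unchanged.
#'
#' @param base_model a fitted [pix2pix()] base model.
#' @param patient `list(ct = ct_volume, cbcts = list of ct_volume)`.
#' @param n_cbct_sets number of CBCT sets used (1 -> "model 1", 2 ->
#'   "model 2").
#' @param config a [study_b_config()].
#' @return a `pix2pix` patient-specific model.
#' @export
make_patient_specific <- function(base_model, patient, n_cbct_sets = 1L,
                                  config = study_b_config()) {
  if (n_cbct_sets > length(patient$cbcts))
    stop("'n_cbct_sets' exceeds the available CBCT sets")
  pairs <- build_training_pairs(patient$ct,
                                patient$cbcts[seq_len(n_cbct_sets)],
                                config$prep)
  cfg <- config$transfer
  cfg$seed <- derive_seed(config$seed, "transfer", n_cbct_sets)
  transfer_learn(base_model, pairs, cfg,
                 label = sprintf("Patient-specific model %d", n_cbct_sets))
}

#' Run a model over a whole CBCT volume
#'
#' Slice-wise inference preserving slice count, order and thickness.
#'
#' @param model a `pix2pix` model.
#' @param cbct_vol a [ct_volume()].
#' @return a [ct_volume()] of synthetic-CT slices.
#' @export
infer_volume <- function(model, cbct_vol) predict(model, cbct_vol)
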