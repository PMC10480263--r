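test_that("the full-depth generator reproduces the 61-layer listing", {
  g <- build_generator(generator_spec(input_size = 256, base_filters = 4,
                                      encoder_depth = 8))
  kinds <- generator_layer_kinds(g)
  expect_length(kinds, 61)
  expect_identical(kinds, table1_sequence)
  # 4d parameterised layers: 8 + 7 + 8 + 8 + 1
  expect_length(cbctrepair:::param_layer_indices(g), 32)
})

test_that("generator forward preserves shape and halves resolution per stage", {
  spec <- generator_spec(input_size = 256, base_filters = 4,
                         encoder_depth = 8)
  g <- build_generator(spec)
  x <- array(0, c(256, 256, 1))
  fw <- cbctrepair:::net_forward(g, x)
  expect_identical(dim(fw$out), c(256L, 256L, 1L))
  # bottleneck activation: input_size / 2^depth = 1 at 256 with depth 8
  enc_dims <- t(vapply(fw$acts[1:24], dim, integer(3)))
  expect_identical(min(enc_dims[, 1]), 1L)
  # at desk scale the bottleneck is 2 px
  g64 <- build_generator(desk_generator_spec(64))
  fw64 <- cbctrepair:::net_forward(g64, array(0, c(64, 64, 1)))
  expect_identical(dim(fw64$out), c(64L, 64L, 1L))
  expect_identical(min(t(vapply(fw64$acts, dim, integer(3)))[, 1]), 2L)
  expect_error(generator_spec(input_size = 100, encoder_depth = 5),
               "bottleneck")
})

test_that("the patch discriminator makes grid decisions with a 70 px field", {
  d <- build_discriminator(64, base_filters = 8)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  fw <- cbctrepair:::net_forward(d, x)
  expect_gt(dim(fw$out)[1], 1)
  expect_gt(dim(fw$out)[2], 1)
  expect_identical(receptive_field(d), 70)
  # deterministic construction per seed
  expect_identical(layer_checksums(build_discriminator(64, 8, seed = 9)),
                   layer_checksums(build_discriminator(64, 8, seed = 9)))
  expect_false(all(layer_checksums(build_discriminator(64, 8, seed = 9)) ==
                     layer_checksums(build_discriminator(64, 8, seed = 10))))
})

test_that("HU normalisation maps endpoints and round-trips", {
  expect_equal(normalize_hu(-1024), -1)
  expect_equal(normalize_hu(3071), 1)
  set.seed(4)
  img <- matrix(runif(256, -1024, 3071), 16)
  expect_lt(max(abs(denormalize_hu(normalize_hu(img)) - img)), 1e-3)
})

test_that("adversarial training reduces the generator L1 term and is seeded", {
  vol <- make_cohort(1, 4, fix_spec32, seed = 8)[[1]]
  pairs <- sim_full_pairs(vol, fix_params32, seed = 2)
  cfg <- train_config(epochs = 10, seed = 1)
  m <- pix2pix(pairs, config = cfg)
  expect_s3_class(m, "pix2pix")
  expect_lt(m$history$g_l1[10], m$history$g_l1[1])
  expect_identical(nrow(m$history), 10L)
  # bit-identical rerun under the same config and seed
  m2 <- pix2pix(pairs, config = cfg)
  expect_identical(layer_checksums(m), layer_checksums(m2))
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("inference preserves shape, clamps to HU range and maps batches", {
  vol <- make_cohort(1, 3, fix_spec32, seed = 8)[[1]]
  pairs <- sim_full_pairs(vol, fix_params32, seed = 2)
  m <- pix2pix(pairs[1], config = train_config(epochs = 2, seed = 1))
  out <- predict(m, pairs[[1]]$input_img)
  expect_identical(dim(out), dim(pairs[[1]]$input_img))
  expect_gte(min(out), -1024)
  expect_lte(max(out), 3071)
  outs <- predict(m, lapply(pairs, `[[`, "input_img"))
  expect_length(outs, 3)
  expect_identical(outs[[2]], predict(m, pairs[[2]]$input_img))
  # deterministic at inference (dropout off, fixed model)
  expect_identical(out, predict(m, pairs[[1]]$input_img))
})

test_that("transfer learning retrains exactly the final parameterised layers", {
  vol <- make_cohort(1, 2, fix_spec32, seed = 9)[[1]]
  pairs <- sim_full_pairs(vol, fix_params32, seed = 3)
  base <- pix2pix(pairs, config = train_config(epochs = 2, seed = 1))
  cs_base <- layer_checksums(base)

  ps <- transfer_learn(base, pairs, transfer_config(epochs = 1, seed = 5))
  cs_ps <- layer_checksums(ps)
  changed <- which(cs_base != cs_ps)
  expect_identical(length(changed), 2L)
  # the changed layers are the last two parameterised ones (final decoder
  # batch normalisation + terminal convolution)
  expect_identical(unname(changed), c(length(cs_base) - 1L, length(cs_base)))
  # every frozen layer is bit-identical, checked layer by layer
  for (k in seq_len(length(cs_base) - 2)) {
    expect_identical(cs_ps[[k]], cs_base[[k]])
  }
  # the base model object is untouched
  expect_identical(layer_checksums(base), cs_base)
  # zero-epoch transfer is a no-op on all checksums
  expect_identical(layer_checksums(
    transfer_learn(base, pairs, transfer_config(epochs = 0))), cs_base)
  expect_error(
    transfer_learn(base, pairs,
                   transfer_config(n_trainable_param_layers = 99, epochs = 1)),
    "trainable")
})

test_that("a generator overfits the identity mapping on one batch", {
  img <- fix_img32
  pairs <- list(structure(list(input_img = img, target_img = img,
                               patient_id = "P", slice_index = 1,
                               stage_tag = "t"),
                          class = "paired_sample"))
  m <- pix2pix(pairs, config = train_config(epochs = 300, seed = 1))
  # training-mode L1 keeps a floor from active dropout and the
  # adversarial term; an order-of-magnitude drop shows the identity was
  # learned
  expect_lt(utils::tail(m$history$g_l1, 1), 0.15 * m$history$g_l1[1])
  out <- predict(m, img)
  expect_lt(mae_slice(out, img), 200)
})
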