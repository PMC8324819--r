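test_that("initial conditions stay in their documented ranges with unit mass", {
  for (name in c("flux", "bubble", "wealth")) {
    ex <- fp_example(name)
    set.seed(5)
    for (k in 1:5) {
      ic <- sample_initial_state(ex)
      expect_equal(sum(ic$P) * ex$grid$dx, 1, tolerance = 1e-9)
      if (name == "flux") {
        expect_true(ic$x0 >= 0.04 && ic$x0 <= 0.08)
        expect_true(ic$t_init >= 0.03 && ic$t_init <= 0.05)
      } else {
        lo <- if (name == "bubble") 0.4 else 0.3
        hi <- if (name == "bubble") 0.8 else 0.7
        expect_true(ic$mean >= lo && ic$mean <= hi)
        expect_true(ic$sd >= 0.05 && ic$sd <= 0.1)
        expect_identical(ic$t_init, 0)
      }
    }
  }
})

test_that("clean sequences have the requested shape and near-unit mass", {
  set.seed(8)
  ex <- fp_example("flux")
  cl <- generate_sequences(ex, n_sequences = 3, n_times = 5)
  expect_length(cl, 3)
  expect_identical(dim(cl[[1]]), c(5L, 110L))
  # analytic Gaussian tails leave at most a few 1e-3 of mass outside
  masses <- unlist(lapply(cl, function(m) rowSums(m) * ex$grid$dx))
  expect_true(all(abs(masses - 1) < 5e-3))
  exw <- fp_example("wealth")
  clw <- generate_sequences(exw, 2, 10)
  mw <- unlist(lapply(clw, function(m) rowSums(m) * exw$grid$dx))
  expect_true(all(abs(mw - 1) < 1e-3))
  # the bubble process is absorbed at small lengths: mass only decreases
  exb <- fp_example("bubble")
  clb <- generate_sequences(exb, 1, 50)
  mb <- rowSums(clb[[1]]) * exb$grid$dx
  expect_true(all(diff(mb) < 1e-5))   # no material gain, absorption only
  expect_lt(mb[50], mb[1])
  expect_true(all(mb <= 1 + 1e-5))
  expect_error(generate_sequences(ex, 0, 5), class = "fpinverse_invalid")
})

test_that("multiplicative noise behaves like its defining model", {
  set.seed(9)
  ex <- fp_example("flux")
  cl <- generate_sequences(ex, 4, 20)
  expect_identical(add_noise(cl[[1]], 0), cl[[1]])
  withzero <- cl[[1]]
  withzero[, 1:3] <- 0
  noisy <- add_noise(withzero, 0.5)
  expect_true(all(noisy[, 1:3] == 0))
  # measured relative deviation concentrates near W
  ratio <- fpinverse:::rel_l2(add_noise(cl, 0.05), cl)
  expect_equal(ratio, 0.05, tolerance = 0.05)
  expect_error(add_noise(cl[[1]], -1), class = "fpinverse_invalid")
})

test_that("noise calibration hits the target ratio", {
  set.seed(10)
  ex <- fp_example("flux")
  cl <- generate_sequences(ex, 6, 30)
  W <- calibrate_noise(cl, 0.01)
  expect_equal(W, 0.01, tolerance = 0.05)
  measured <- fpinverse:::rel_l2(add_noise(cl, W), cl)
  expect_equal(measured, 0.01, tolerance = 0.05)
  expect_identical(calibrate_noise(cl, 0), 0)
})

test_that("the train/test split is seeded, sized and validated", {
  set.seed(11)
  ex <- fp_example("flux")
  cl <- generate_sequences(ex, 12, 4)
  no <- add_noise(cl, 0.01)
  set.seed(3); s1 <- split_dataset(no, cl, 10)
  set.seed(3); s2 <- split_dataset(no, cl, 10)
  expect_identical(s1$train_idx, s2$train_idx)
  expect_length(s1$train, 10)
  expect_length(s1$test, 2)
  expect_error(split_dataset(no, cl, 12), class = "fpinverse_invalid")
  expect_error(split_dataset(no, cl[-1], 5), class = "fpinverse_invalid")
})

test_that("datasets are reproducible bit-for-bit from their seed", {
  d1 <- fp_simulate(fp_example("wealth"), n_sequences = 5, n_times = 6,
                    n_train = 4, seed = 77)
  d2 <- fp_simulate(fp_example("wealth"), n_sequences = 5, n_times = 6,
                    n_train = 4, seed = 77)
  expect_identical(d1$train, d2$train)
  expect_identical(d1$W, d2$W)
  expect_identical(d1$train_idx, d2$train_idx)
})

test_that("dataset serialization round-trips", {
  ds <- fp_simulate(fp_example("flux"), n_sequences = 4, n_times = 5,
                    n_train = 3, seed = 12)
  for (fmt in c("tsv", "rds")) {
    dir <- file.path(tempdir(), paste0("fpds_", fmt))
    write_fp_dataset(ds, dir, format = fmt)
    back <- read_fp_dataset(dir)
    expect_equal(back$train, ds$train, tolerance = 0)
    expect_equal(back$clean_test, ds$clean_test, tolerance = 0)
    expect_identical(back$example$name, "flux")
    expect_equal(back$W, ds$W)
    unlink(dir, recursive = TRUE)
  }
})
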