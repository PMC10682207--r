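test_that("grid enumeration matches the factorial structure", {
  scenes <- build_parameter_grid(parameter_grid())
  expect_equal(nrow(scenes), 2100) # 6 * 2 * 7 * 5 * 5
  expect_equal(sort(unique(scenes$cab)), seq(25, 50, by = 5))
  expect_equal(sort(unique(scenes$ala)), seq(0, 60, by = 15))
  # lexicographic order: cab slowest, ala fastest
  expect_equal(scenes$cab, rep(seq(25, 50, by = 5), each = 350))
  expect_equal(scenes$ala[1:5], seq(0, 60, by = 15))
  # each target level appears 350 times
  expect_true(all(table(scenes$cab) == 350))

  # degenerate grid: one scene
  g1 <- parameter_grid(
    cab = c(40, 40, 5), n_structure = c(1, 1, 1),
    lai = c(3, 3, 1), soil_scale = c(1, 1, 1), ala = c(30, 30, 5)
  )
  expect_equal(nrow(build_parameter_grid(g1)), 1)

  expect_error(parameter_grid(cab = c(25, 50, 0)), "step")
  expect_error(parameter_grid(cab = c(50, 25, 5)), "step > 0 and max >= min")
})

test_that("enumeration count equals the product of level counts for random grids", {
  for (seed in 1:10) {
    tr <- withr::with_seed(seed, {
      lapply(1:5, function(i) {
        lo <- runif(1, 0, 10)
        step <- runif(1, 0.1, 2)
        k <- sample(1:6, 1)
        c(lo, lo + step * (k - 1), step)
      })
    })
    g <- parameter_grid(
      cab = tr[[1]], n_structure = tr[[2]] + c(1, 1, 0),
      lai = tr[[3]], soil_scale = tr[[4]], ala = pmin(tr[[5]], 90)
    )
    expected <- prod(vapply(
      list(g$cab, g$n_structure, g$lai, g$soil_scale, g$ala),
      function(t) floor((t[2] - t[1]) / t[3] + 1e-9) + 1, numeric(1)
    ))
    expect_equal(nrow(build_parameter_grid(g)), expected)
  }
})

test_that("simulated datasets carry one spectrum per scene and cab as target", {
  g <- parameter_grid(
    cab = c(25, 45, 20), n_structure = c(1.5, 1.5, 0.5),
    lai = c(2, 4, 2), soil_scale = c(0.8, 0.8, 0.1), ala = c(30, 30, 15)
  )
  d <- simulate_dataset(g)
  expect_equal(nrow(d), 4)
  expect_equal(length(spectra_wavelengths(d)), 651)
  expect_true(all(spectra_matrix(d) >= 0 & spectra_matrix(d) <= 1))
  expect_equal(sort(unique(d$cab)), c(25, 45))

  # one-scene grid
  g1 <- parameter_grid(
    cab = c(40, 40, 5), n_structure = c(1, 1, 1),
    lai = c(3, 3, 1), soil_scale = c(1, 1, 1), ala = c(30, 30, 5)
  )
  expect_equal(nrow(simulate_dataset(g1)), 1)
})

test_that("target summaries reproduce the dataset-statistics table exactly", {
  lcc <- rep(seq(25, 50, by = 5), each = 350)
  s <- describe_target(lcc)
  expect_equal(s$n, 2100)
  expect_equal(s$min, 25)
  expect_equal(s$q1, 30)
  expect_equal(s$median, 37.5)
  expect_equal(s$q3, 45)
  expect_equal(s$max, 50)
  expect_equal(s$mean, 37.5)
  expect_equal(round(s$sd, 2), 8.54)
  expect_equal(round(s$cv, 3), 0.228)

  # constant vector
  s0 <- describe_target(rep(7, 10))
  expect_equal(s0$sd, 0)
  expect_equal(c(s0$q1, s0$median, s0$q3), c(7, 7, 7))

  # the quartile cut points fall strictly inside level blocks, so every
  # standard quantile convention agrees on this dataset
  for (type in 1:9) {
    q <- quantile(lcc, c(0.25, 0.75), type = type, names = FALSE)
    expect_equal(q, c(30, 45))
  }

  expect_error(describe_target(5), "at least 2")
})

test_that("random splits have the printed sizes and are exact partitions", {
  s <- split_dataset(69, 0.75, seed = 1)
  expect_equal(length(s$train), 52)
  expect_equal(length(s$validation), 17)

  s2 <- split_dataset(2100, seed = 3, explicit_counts = c(1569, 531))
  expect_equal(length(s2$train), 1569)
  expect_equal(length(s2$validation), 531)

  # bijection: indices partition 1..n; identical seed -> identical split
  for (seed in 1:5) {
    sp <- split_dataset(101, 0.75, seed = seed)
    expect_equal(sort(c(sp$train, sp$validation)), 1:101)
    expect_identical(sp, split_dataset(101, 0.75, seed = seed))
  }
  expect_false(identical(
    split_dataset(101, 0.75, seed = 1)$train,
    split_dataset(101, 0.75, seed = 2)$train
  ))

  s4 <- split_dataset(4, 0.75, seed = 9)
  expect_equal(length(s4$train), 3)
  expect_equal(length(s4$validation), 1)

  expect_error(split_dataset(10, explicit_counts = c(5, 4)), "summing")
  expect_error(split_dataset(10, train_fraction = 1), "train_fraction")
})

test_that("SPAD/LCC conversion is the printed affine map with exact inverse", {
  expect_equal(spad_to_lcc(36), 0.709 * 36 - 1.576)
  expect_equal(spad_to_lcc(36), 23.948)
  expect_warning(v0 <- spad_to_lcc(0), "extrapolation")
  expect_equal(v0, -1.576)
  x <- c(5, 20, 36, 41.99)
  expect_equal(lcc_to_spad(spad_to_lcc(x)), x, tolerance = 1e-12)
  expect_error(spad_to_lcc(-1), "spad")
})
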