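test_that("degenerate generator lies exactly on the binding curve", {
  p <- test_case_params(kd_true = 5000, b_true = 780, u_true = 800,
                        noise_sd = 0, pipette_sd_ul = 0,
                        outlier_fraction = 0, repeats = 2, seed = 5)
  d <- generate_dataset(p)
  mu <- mass_action_response(d$concentration_nM, kd = 5000, u = 800,
                             b = 780, cfl = 50)
  expect_equal(d$response, mu)
  expect_equal(d$true_concentration_nM, d$concentration_nM)
  expect_false(any(d$is_outlier))
})

test_that("outlier count is exactly the floor of the contaminated fraction", {
  p3 <- test_case_params(5000, 780, 800, repeats = 3, seed = 1)
  expect_identical(sum(generate_dataset(p3)$is_outlier), 9L)  # floor(.2*48)
  for (frac in c(0, 0.1, 0.33, 1)) {
    p <- test_case_params(5000, 780, 800, repeats = 2, seed = 2,
                          outlier_fraction = frac)
    expect_identical(sum(generate_dataset(p)$is_outlier),
                     as.integer(floor(frac * 32)))
  }
})

test_that("outliers span the U-B range with the 25% margin and x is the targeted concentration", {
  p <- test_case_params(5000, 780, 800, repeats = 10, seed = 8)
  d <- generate_dataset(p)
  out <- d$response[d$is_outlier]
  m <- 0.25 * abs(780 - 800)
  expect_true(all(out >= 780 - m & out <= 800 + m))
  expect_identical(d$concentration_nM,
                   rep(targeted_concentrations(100 * 5000, 15), 10))
  expect_false(identical(d$concentration_nM, d$true_concentration_nM))
})

test_that("generation is deterministic in the seed and replicates differ", {
  p <- test_case_params(500, 780, 800, repeats = 3, seed = 21)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1, d2)
  expect_false(identical(d1$true_concentration_nM[1:16],
                         d1$true_concentration_nM[17:32]))
  expect_identical(sort(unique(d1$replicate)), 1:3)
})

test_that("non-outlier residuals against the true curve look normal", {
  p <- test_case_params(5000, 780, 800, noise_sd = 1, repeats = 10,
                        seed = 31)
  d <- generate_dataset(p)
  mu <- mass_action_response(d$true_concentration_nM, kd = 5000, u = 800,
                             b = 780, cfl = 50)
  r <- (d$response - mu)[!d$is_outlier]
  expect_gt(shapiro.test(r)$p.value, 0.01)
  expect_lt(abs(sd(r) - 1), 0.2)
})

test_that("datasets round-trip through delimited text", {
  d <- generate_dataset(test_case_params(500, 780, 800, repeats = 3,
                                         seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_titration(d, f)
  d2 <- read_titration(f)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)  # ground truth is not serialized
  expect_identical(nrow(d2), 48L)
  expect_identical(sort(unique(d2$replicate)), 1:3)
})

test_that("unknown columns survive the round trip", {
  d <- titration_data(1, c(100, 50), c(800, 799))
  d$note <- c("a", "b")
  f <- withr::local_tempfile(fileext = ".csv")
  write_titration(d, f)
  expect_identical(read_titration(f)$note, c("a", "b"))
})

test_that("malformed files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), f)
  expect_error(read_titration(f))
  writeLines(c("replicate,concentration_nM,response",
               "1,100,800", "1,oops,799"), f)
  expect_error(read_titration(f), "line 2")
  writeLines(c("replicate,concentration_nM,response", "1,-5,800"), f)
  expect_error(read_titration(f), "concentration")
  writeLines(c("replicate,response", "1,800"), f)
  expect_error(read_titration(f), "concentration_nM")
  expect_error(read_titration(file.path(tempdir(), "no-such-file.csv")))
})
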