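test_that("curve files are parsed, sorted and round-tripped", {
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# synthetic demo curve",
               "# cal BP, 14C BP, error",
               "12000,10200,30",
               "12500,10600,35",
               "13000,11050,40"), path)
  curve <- read_calibration_curve(path)
  expect_s3_class(curve, "cal_curve")
  expect_equal(curve$cal_age, c(12000, 12500, 13000))
  expect_equal(curve$c14_age, c(10200, 10600, 11050))
  expect_equal(curve$error, c(30, 35, 40))

  # descending record order and whitespace separation give the same curve
  path2 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("13000 11050 40", "12500 10600 35", "12000 10200 30"), path2)
  expect_equal(read_calibration_curve(path2), curve)

  # extra columns (Delta-14C etc.) are ignored
  path3 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("12000,10200,30,123,4", "13000,11050,40,117,5"), path3)
  expect_equal(read_calibration_curve(path3)$c14_age, c(10200, 11050))

  # write -> read is bit-for-bit
  out <- withr::local_tempfile(fileext = ".14c")
  write_calibration_curve(curve, out)
  expect_identical(read_calibration_curve(out), curve)
})

test_that("malformed curve files fail with informative errors", {
  path <- withr::local_tempfile()
  writeLines(c("# header", "12000,10200,30", "12500,oops,35",
               "13000,11050,40"), path)
  expect_error(read_calibration_curve(path), "line 3")

  short <- withr::local_tempfile()
  writeLines(c("# only one record", "12000,10200,30"), short)
  expect_error(read_calibration_curve(short), "fewer than 2")

  expect_error(read_calibration_curve(file.path(tempdir(), "nope.14c")),
               "no such file")
})

test_that("synthesized curves honour their analytic definition", {
  ident <- identity_curve(step = 5)
  expect_equal(ident$c14_age, ident$cal_age)
  expect_equal(ident$error, rep(0, length(ident$cal_age)))
  expect_length(synthesize_curve(c(12000, 13000), step = 5)$cal_age, 201)

  # strong wiggles make the curve non-invertible: some radiocarbon age is
  # attained at more than one calendar age within the span
  folded <- folded_curve()
  expect_true(any(diff(folded$c14_age) < 0))
  expect_gt(max(tabulate(match(round(folded$c14_age),
                               unique(round(folded$c14_age))))), 1)

  expect_error(synthesize_curve(c(12000, 13000), wiggle_amplitude = 10,
                                wiggle_period = 0), "wiggle_period")
  expect_error(synthesize_curve(c(12000, 12000)), "interval")
  expect_error(synthesize_curve(c(12000, 13000), step = 0), "step")
})

test_that("back-calibration interpolates linearly and refuses to extrapolate", {
  expect_equal(back_calibrate(identity_curve(), 12500), 12500)

  two <- cal_curve(c(12000, 12010), c(10200, 10220), c(0, 0))
  expect_equal(back_calibrate(two, 12005), 10210)

  expect_error(back_calibrate(identity_curve(), 11999), "outside curve span")
  expect_error(back_calibrate(identity_curve(), 13000.5), "outside")
})

test_that("calibration is the gridded Gaussian posterior", {
  ident <- identity_curve()
  dens <- calibrate(ident, c14_date(12500, lab_error = 50))
  expect_equal(sum(dens$mass), 1, tolerance = 1e-12)
  expect_equal(density_mode(dens), 12500)
  dsd <- sqrt(sum(dens$mass * (dens$cal_age - density_mean(dens))^2))
  expect_equal(dsd, 50, tolerance = 1)

  # normalization holds for arbitrary dates on a realistic wiggle curve
  wig <- wiggle_curve()
  set.seed(1)
  for (c14 in runif(5, 10400, 11400)) {
    d <- calibrate(wig, c14_date(c14, 50))
    expect_equal(sum(d$mass), 1, tolerance = 1e-9)
    expect_true(all(d$mass >= 0))
  }

  expect_error(calibrate(ident, c14_date(50000, 10)), "incompatible")
  expect_error(calibrate(ident, c14_date(12500, 50), grid_step = 0),
               "grid_step")
})

test_that("non-invertible curves give multimodal densities matching brute force", {
  folded <- folded_curve()
  # 14C age near the fold level is reached on several calendar branches
  date <- c14_date(12500, lab_error = 20)
  dens <- calibrate(folded, date)

  # independent brute-force evaluation of the unnormalized posterior
  mu <- approx(folded$cal_age, folded$c14_age, xout = dens$cal_age)$y
  w <- dnorm(date$c14_age, mu, sqrt(date$lab_error^2))
  expect_equal(dens$mass, w / sum(w), tolerance = 1e-12)

  n_modes <- function(m) {
    sum(diff(sign(diff(m))) == -2)
  }
  expect_gte(n_modes(dens$mass), 2)
  expect_equal(n_modes(dens$mass), n_modes(w))
})

test_that("curve fixtures resolve by tag and densities export as text", {
  expect_s3_class(resolve_curve("fixture:identity"), "cal_curve")
  intcal_like <- resolve_curve("fixture:intcal_like")
  expect_equal(back_calibrate(intcal_like, 12500), 12500 - 1850,
               tolerance = 61)
  expect_error(resolve_curve("fixture:unknown"), "unknown curve fixture")

  shipped <- system.file("extdata", "synthetic_wiggle_curve.14c",
                         package = "pewmachron")
  expect_gt(nchar(shipped), 0)
  sc <- read_calibration_curve(shipped)
  expect_equal(range(sc$cal_age), c(12000, 13000))
  expect_equal(sc$error, rep(40, length(sc$error)))

  d <- calibrate(identity_curve(), c14_date(12400, 40))
  path <- withr::local_tempfile(fileext = ".csv")
  write_density(d, path)
  back <- read.csv(path)
  expect_equal(back$mass, d$mass)
})
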