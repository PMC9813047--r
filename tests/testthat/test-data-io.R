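test_that("counts tables round-trip through write and read exactly", {
  tt <- tiny_tables()
  path <- write_tmp_csv(tt$counts)
  back <- read_counts(path, "fce", years = 2012:2013, bands = tiny_bands())
  expect_equal(back$year, tt$counts$year[order(tt$counts$year)])
  expect_identical(attr(back, "setting"), "fce")
  # identity on values irrespective of row order
  key <- function(d) d[order(d$year, d$age_band), c("year", "age_band", "count")]
  expect_equal(unname(as.matrix(key(back))), unname(as.matrix(key(tt$counts))))

  p2 <- tempfile(fileext = ".csv")
  write_counts(back, p2)
  again <- read_counts(p2, "fce", years = 2012:2013, bands = tiny_bands())
  expect_equal(again, back)
})

test_that("malformed counts files are rejected", {
  tt <- tiny_tables()
  dup <- rbind(tt$counts, tt$counts[1, ])
  expect_error(read_counts(write_tmp_csv(dup), "fce"), "duplicate")

  neg <- tt$counts
  neg$count[2] <- -1L
  expect_error(read_counts(write_tmp_csv(neg), "fce"), "negative")

  bad <- tt$counts
  bad$age_band[1] <- "fifty"
  expect_error(read_counts(write_tmp_csv(bad), "fce", bands = tiny_bands()),
               "unknown age-band")
})

test_that("missing cells are an error unless zero-fill is configured", {
  tt <- tiny_tables()
  holey <- tt$counts[-1, ]
  path <- write_tmp_csv(holey)
  expect_error(read_counts(path, "fce", years = 2012:2013,
                           bands = tiny_bands()), "missing")
  filled <- read_counts(path, "fce", years = 2012:2013,
                        bands = tiny_bands(), fill_missing = "zero")
  expect_equal(nrow(filled), 4L)
  expect_equal(sum(filled$count), sum(holey$count))
})

test_that("life-table schedules round-trip and are validated", {
  sched <- const_schedule(0.02, width = 5, terminal = 100)
  path <- tempfile(fileext = ".csv")
  write_life_table(sched, path)
  back <- read_life_table(path)
  expect_s3_class(back, "mortality_schedule")
  expect_equal(back$age, sched$age)
  expect_equal(back$mx, sched$mx)
  expect_true(is.infinite(back$n[nrow(back)]))

  expect_error(read_life_table(write_tmp_csv(data.frame(age = c(5, 10),
                                                        mx = 0.01))),
               "start at age 0")
  expect_error(read_life_table(write_tmp_csv(data.frame(age = c(0, 5),
                                                        mx = c(0.01, -1)))),
               "negative")
})

test_that("qx-only schedules are accepted with terminal qx = 1", {
  df <- data.frame(age = c(0, 1, seq(5, 90, 5)),
                   qx = c(0.004, 0.001, rep(0.02, 17), 1))
  back <- read_life_table(write_tmp_csv(df))
  expect_true(all(back$mx > 0))
  lt <- build_life_table(back)
  expect_equal(lt$qx[nrow(lt)], 1)
  # recovered closed-interval mx reproduce the input qx through the builder
  expect_equal(lt$qx[-nrow(lt)], df$qx[-nrow(df)], tolerance = 1e-10)

  df$qx[5] <- 1.2
  expect_error(read_life_table(write_tmp_csv(df)), "qx outside")
  df$qx[5] <- 0.02
  df$qx[nrow(df)] <- 0.5
  expect_error(read_life_table(write_tmp_csv(df)), "terminal")
})

test_that("run configuration reads with validation and defaults", {
  cfg <- read_run_config(example_config_path())
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$smr, 1.18)
  expect_equal(cfg$years, 2012:2018)
  expect_equal(cfg$icd_codes,
               c("M47.1", "M50.0", "M99.3", "M99.4", "M99.5"))
  expect_true(cfg$conversion$lower <= cfg$conversion$pooled)
  expect_equal(length(cfg$scc_curve), 5L)

  bad <- tempfile(fileext = ".yaml")
  writeLines("smr: -2", bad)
  expect_error(read_run_config(bad), "smr")
})
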