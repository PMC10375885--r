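test_that("population CSV reads into a validated table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,sex,age_start,age_end,population",
               "A,female,60,69,1000"), path)
  pop <- read_population_csv(path, year = 2021)
  expect_equal(nrow(pop), 1L)
  expect_equal(pop$population, 1000)
  expect_equal(attr(pop, "year"), 2021)

  writeLines(c("country,sex,age_start,population", "A,female,60,1000"), path)
  expect_error(read_population_csv(path), class = "coi_schema_error")

  writeLines(c("country,sex,age_start,age_end,population",
               "A,male,60,69,-5"), path)
  expect_error(read_population_csv(path), class = "coi_validation_error")

  # open 90+ band overlapping a closed 85-95 band
  writeLines(c("country,sex,age_start,age_end,population",
               "A,male,90,,10", "A,male,85,95,5"), path)
  expect_error(read_population_csv(path), class = "coi_validation_error")
})

test_that("prevalence CSV validation rejects out-of-range, duplicate and gappy schedules", {
  path <- withr::local_tempfile(fileext = ".csv")
  ok <- c("age_start,age_end,sex,prevalence",
          "60,69,male,0.02", "70,,male,0.1",
          "60,69,female,0.02", "70,,female,0.1")
  writeLines(ok, path)
  sched <- read_prevalence_csv(path)
  expect_equal(sched$prevalence[sched$sex == "female" & sched$age_start == 60], 0.02)

  writeLines(sub("60,69,female,0.02", "60,69,female,1.5", ok), path)
  expect_error(read_prevalence_csv(path), class = "coi_validation_error")

  writeLines(c(ok, "60,69,male,0.03"), path)
  expect_error(read_prevalence_csv(path), class = "coi_validation_error")

  # gap: 70-79 missing while 80+ present
  gap <- c("age_start,age_end,sex,prevalence",
           "60,69,male,0.02", "80,,male,0.1",
           "60,69,female,0.02", "80,,female,0.1")
  writeLines(gap, path)
  expect_error(read_prevalence_csv(path), class = "coi_validation_error")

  # terminal band must be open
  closed <- c("age_start,age_end,sex,prevalence",
              "60,69,male,0.02", "60,69,female,0.02")
  writeLines(closed, path)
  expect_error(read_prevalence_csv(path), class = "coi_validation_error")
})

test_that("economics CSV keeps missing values and rejects unknown income classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,gdp_pc_ppp,income_class,monthly_wage,gdp_total",
               "Jordan,9000,upper_middle,475,4.5e10",
               "Kuwait,,high,,1.3e11"), path)
  econ <- read_economics_csv(path)
  expect_equal(econ$monthly_wage[econ$country == "Jordan"], 475)
  expect_true(is.na(econ$gdp_pc_ppp[econ$country == "Kuwait"]))
  expect_false(any(econ$imputed_gdp))

  writeLines(c("country,gdp_pc_ppp,income_class,monthly_wage,gdp_total",
               "X,1000,middle,100,1e9"), path)
  expect_error(read_economics_csv(path), class = "coi_validation_error")
})

test_that("factor CSV requires all four income classes with positive factors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("income_class,factor", "low,0.1", "lower_middle,0.08",
               "upper_middle,0.06", "high,0.04"), path)
  expect_equal(nrow(read_factors_csv(path)), 4L)
  writeLines(c("income_class,factor", "low,0.1"), path)
  expect_error(read_factors_csv(path), class = "coi_validation_error")
})

test_that("write-read-write round trips are byte-stable for all input tables", {
  inp <- generate_inputs(synth_config(seed = 11, n_countries = 5))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.csv"); p2 <- file.path(dir, "b.csv")

  write_population_csv(inp$population, p1)
  write_population_csv(read_population_csv(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  expect_equal(read_population_csv(p2)$population, inp$population$population)

  write_prevalence_csv(inp$schedule, p1)
  write_prevalence_csv(read_prevalence_csv(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  write_economics_csv(inp$economics, p1)
  write_economics_csv(read_economics_csv(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  write_factors_csv(inp$factors, p1)
  write_factors_csv(read_factors_csv(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("result writing is deterministic and ordered by country", {
  s <- run_synth(3, n = 4L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_report(s$res$costs, s$res$summaries, out_dir = d1)
  build_report(s$res$costs, s$res$summaries, out_dir = d2)
  files <- list.files(d1)
  expect_true(all(c("prevalence.csv", "direct.csv", "indirect.csv",
                    "totals.csv", "pct_gdp.csv") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  direct <- utils::read.csv(file.path(d1, "direct.csv"))
  body <- direct$country[direct$country != "TOTAL"]
  expect_identical(body, sort(body))
  expect_identical(direct$country[nrow(direct)], "TOTAL")
})

test_that("empty result sets still produce headers-only files", {
  s <- run_synth(3, n = 2L)
  empty_costs <- s$res$costs[0, ]
  empty_sum <- s$res$summaries[0, ]
  dir <- withr::local_tempdir()
  build_report(empty_costs, empty_sum, out_dir = dir)
  direct <- utils::read.csv(file.path(dir, "direct.csv"))
  expect_equal(nrow(direct), 1L)  # only the TOTAL row
})

test_that("shipped synthetic fixtures load through the typed readers", {
  ext <- system.file("extdata", package = "coiburden")
  sched <- read_prevalence_csv(file.path(ext, "prevalence_schedule_synthetic.csv"))
  expect_true(all(diff(sched$prevalence[sched$sex == "male"]) > 0))
  fact <- read_factors_csv(file.path(ext, "direct_cost_factors_synthetic.csv"))
  expect_setequal(fact$income_class, c("low", "lower_middle", "upper_middle", "high"))
})
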