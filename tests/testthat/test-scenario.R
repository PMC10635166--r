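test_that("the oxygen-profile scenario records an expanded anoxic region", {
  out <- withr::local_tempdir()
  manifest <- run_scenario("fig1", out)
  expect_true(all(file.exists(manifest)))
  # manifest completeness: everything in out_dir is listed
  expect_setequal(list.files(out, recursive = TRUE),
                  sub(paste0(out, .Platform$file.sep), "", manifest,
                      fixed = TRUE))
  f_ox <- grep("oxygen_profile", manifest, value = TRUE)
  r0 <- as.numeric(sub("^# r0_mm=", "", readLines(f_ox, n = 1)))
  expect_gt(r0, 0)
  # after FLASH depletion of the full pulse, the zero region is larger
  prof <- solve_steady_oxygen(flash_params(S_ROD = 160))
  fld <- depletion_field(prof, 160)
  t_end <- 10 / 90
  p_end <- oxygen_at(fld, prof$r_mm[prof$r_mm <= 0.5], t_end)
  ps0 <- prof$ps[prof$r_mm <= 0.5]
  expect_true(all(p_end <= ps0))
  expect_gt(sum(p_end == 0), sum(ps0 == 0))
})

test_that("scenario runs are deterministic byte for byte", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_scenario("fig3a", out1)
  run_scenario("fig3a", out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("the dose scenario table matches an explicit dose sweep", {
  out <- withr::local_tempdir()
  manifest <- run_scenario("fig3b", out)
  summ <- jsonlite::read_json(grep("summary", manifest, value = TRUE),
                              simplifyVector = TRUE)$results
  expect_equal(summ$dose, c(5, 10, 15, 20))
  expect_true(all(summ$overall_sf_flash >= summ$overall_sf_conv))
  sw <- sweep_scenario("fig3b", "dose", c(5, 10, 15, 20))
  expect_equal(sw$overall_sf_conv, summ$overall_sf_conv, tolerance = 1e-12)
  expect_equal(sw$overall_sf_flash, summ$overall_sf_flash, tolerance = 1e-12)
})

test_that("the paired-cell scenario shows the differential response", {
  out <- withr::local_tempdir()
  manifest <- run_scenario("fig5", out)
  summ <- jsonlite::read_json(grep("summary", manifest, value = TRUE),
                              simplifyVector = TRUE)$results
  expect_setequal(summ$cell, c("healthy", "tumor"))
  ratio <- summ$overall_sf_flash / summ$overall_sf_conv
  expect_gt(ratio[summ$cell == "healthy"], ratio[summ$cell == "tumor"])
})

test_that("FLASH survival is non-decreasing in the depletion rate", {
  sw <- sweep_scenario("fig3a", "S_ROD", c(0, 15.3, 160))
  expect_equal(sw$value, c(0, 15.3, 160))
  expect_true(all(diff(sw$overall_sf_flash) >= 0))
  # CONV arm is unaffected by the depletion rate
  expect_lt(diff(range(sw$overall_sf_conv)), 1e-12)
})

test_that("sweep validation rejects bad input", {
  expect_error(sweep_scenario("fig3a", "dose", numeric(0)), "non-empty")
  expect_error(sweep_scenario("fig3a", "unknown_knob", 1), "unknown sweep")
  expect_error(scenario_spec("no-such-preset"), "unknown scenario")
})

test_that("the command-line front end runs a scenario end to end", {
  exe <- file.path(find.package("flashros"), "exec", "flashros")
  expect_true(file.exists(exe))
  out <- withr::local_tempdir()
  res <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2(file.path(R.home("bin"), "Rscript"),
            c(shQuote(exe), "steady-oxygen", "--out", shQuote(out),
              "--srod", "15.3"),
            stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(file.path(out, "oxygen_profile.csv")))
  expect_match(paste(res, collapse = "\n"), "anoxic core")
})
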