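test_that("scenario validation names the offending field", {
  d <- model_determinants()$sys_4e3o
  expect_error(
    scenario_config("x",
                    system = list(kind = "model", M_sys = 6L, electrons = 4L),
                    target = list(p = 1L, kind = "mixture",
                                  occ1 = d$occ1, occ2 = d$occ2, w = 1.3)),
    "target.w")
  expect_error(
    scenario_config("x",
                    system = list(kind = "model", M_sys = 6L, electrons = 4L),
                    target = list(p = 3L, kind = "mixture",
                                  occ1 = d$occ1, occ2 = d$occ2, w = 0.5)),
    "target.p")
  expect_error(
    scenario_config("x", system = list(kind = "banana"),
                    target = list(p = 1L, kind = "mixture")),
    "system.kind")
})

test_that("YAML round trip preserves a scenario config", {
  d <- model_determinants()$sys_4e3o
  cfg <- scenario_config("t2_demo",
                         system = list(kind = "model", M_sys = 6L,
                                       electrons = 4L),
                         target = list(p = 1L, kind = "mixture",
                                       occ1 = d$occ1, occ2 = d$occ2, w = 0.5))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = cfg$name, system = cfg$system,
                        target = cfg$target,
                        algorithms = as.list(cfg$algorithms)), f)
  back <- read_scenario(f)
  expect_equal(back$name, "t2_demo")
  expect_equal(back$target$w, 0.5)
  expect_equal(unlist(back$target$occ1), unlist(d$occ1))
  unlink(f)
})

test_that("run_scenario writes deterministic artifacts", {
  d <- model_determinants()$sys_4e3o
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- scenario_config("demo",
                         system = list(kind = "model", M_sys = 6L,
                                       electrons = 4L),
                         target = list(p = 1L, kind = "mixture",
                                       occ1 = d$occ1, occ2 = d$occ2, w = 0.5),
                         algorithms = "pure", output_dir = dir1)
  suppressMessages(run_scenario(cfg))
  for (f in c("demo_result.json", "demo_trace_pure.csv", "demo_evolved_pure.rdm",
              "demo_audit.json"))
    expect_true(file.exists(file.path(dir1, f)))
  j <- jsonlite::read_json(file.path(dir1, "demo_result.json"))
  expect_true(j$pure$d_min < 1e-8)
  expect_equal(j$audit$klyachko_satisfied, 15L)
  # byte-identical rerun
  cfg$output_dir <- dir2
  suppressMessages(run_scenario(cfg))
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = f)
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("scenario_target honors the noise block", {
  d <- model_determinants()$sys_4e3o
  base <- list(kind = "model", M_sys = 6L, electrons = 4L)
  t0 <- scenario_target(scenario_config("a", base,
    list(p = 1L, kind = "mixture", occ1 = d$occ1, occ2 = d$occ2, w = 0.5)))
  tn <- scenario_target(scenario_config("b", base,
    list(p = 1L, kind = "mixture", occ1 = d$occ1, occ2 = d$occ2, w = 0.5,
         noise = list(eps = 1e-2, seed = 3L))))
  expect_equal(as.matrix(t0$target$matrix), as.matrix(t0$clean$matrix))
  dev <- max(abs(as.matrix(tn$target$matrix) - as.matrix(tn$clean$matrix)))
  expect_gt(dev, 1e-4)
  expect_lte(dev, 1e-2)
})

test_that("the scenario grid covers every table cell exactly once", {
  s2 <- ensrep:::.table_scenarios("t2")
  expect_length(s2, 4L)
  s3 <- ensrep:::.table_scenarios("t3")
  expect_length(s3, 4L)
  s5 <- ensrep:::.table_scenarios("t5")
  expect_length(s5, 6L)
  s6 <- ensrep:::.table_scenarios("t6", seeds = 1:5)
  expect_length(s6, 2L * (1L + 5L + 5L))
  s7 <- ensrep:::.table_scenarios("t7", seeds = 1:5)
  expect_length(s7, 2L * 2L * 2L * (1L + 5L + 5L))
  expect_false(anyDuplicated(names(s7)) > 0)
})

test_that("generate_fixtures is idempotent", {
  out <- tempfile()
  p1 <- generate_fixtures(out, seeds = 1:2)
  md5_1 <- tools::md5sum(list.files(out, recursive = TRUE, full.names = TRUE))
  p2 <- generate_fixtures(out, seeds = 1:2)
  md5_2 <- tools::md5sum(list.files(out, recursive = TRUE, full.names = TRUE))
  expect_identical(md5_1, md5_2)
  # four FCIDUMP fixtures present
  expect_length(list.files(out, pattern = "\\.fcidump$"), 4L)
  unlink(out, recursive = TRUE)
})

test_that("reference tables carry the full published grids", {
  rt <- reference_tables()
  expect_named(rt, c("t2", "t3", "t5", "t6", "t7"))
  expect_equal(nrow(rt$t2), 4L)
  expect_equal(rt$t2$pure[rt$t2$system == "4e4o" & rt$t2$w == 0.5], 1.25e-1)
  expect_equal(rt$t3$pure[rt$t3$system == "4e3o" & rt$t3$w == 0.5], 2.00)
  expect_equal(rt$t5$p2_pure[rt$t5$substitution == 1], 4.25)
  expect_equal(nrow(rt$t7), 12L)
})
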