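# Parameter model: loading, validation, clamping, fixtures, small-sample
# rule, derived pooled-indication costs.

test_that("packaged synthetic parameter file loads with the expected structure", {
  p <- load_parameter_set(default_parameter_file())
  expect_s3_class(p, "parameter_set")
  expect_setequal(names(p$indications),
                  c("breast", "colorectal", "NSCLC", "pancreatic", "thyroid",
                    "sarcoma", "neuroendocrine", "MASC", "other"))
  w <- sapply(p$indications, function(i) i$prevalence_weight)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(sapply(p$indications, function(i) i$trial_n)), 121)
  expect_length(attr(p, "clamp_log"), 0)
  # MASC is the biomarker-enriched indication
  prev <- sapply(p$indications, function(i) i$ntrk_prevalence)
  expect_equal(names(which.max(prev)), "MASC")
})

test_that("pooled 'other' care costs equal the weighted average of the rest", {
  p <- load_parameter_set(default_parameter_file())
  rest <- p$indications[setdiff(names(p$indications), "other")]
  w <- sapply(rest, function(i) i$prevalence_weight)
  w <- w / sum(w)
  for (f in c("cost_pf_care", "cost_pd_care")) {
    expect_equal(p$indications$other[[f]],
                 sum(w * sapply(rest, function(i) i[[f]])),
                 tolerance = 1e-9)
  }
  expect_true(p$indications$other$care_costs_derived)
})

test_that("save/load round-trips a parameter set field-for-field", {
  p <- generate_fixture(seed = 11, n_indications = 4)
  for (fmt in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    save_parameter_set(p, path)
    q <- load_parameter_set(path)
    for (n in names(p$indications)) {
      expect_equal(unclass(q$indications[[n]]), unclass(p$indications[[n]]),
                   tolerance = 1e-12)
    }
    expect_equal(unclass(q$globals), unclass(p$globals), tolerance = 1e-12)
    expect_setequal(names(q$distributions), names(p$distributions))
    for (k in names(p$distributions)) {
      expect_equal(q$distributions[[k]]$family, p$distributions[[k]]$family)
      expect_equal(q$distributions[[k]]$params, p$distributions[[k]]$params,
                   tolerance = 1e-12)
    }
  }
})

test_that("CSV input with one row per indication loads", {
  p <- generate_fixture(seed = 3, n_indications = 3)
  df <- do.call(rbind, lapply(p$indications, function(i) {
    as.data.frame(unclass(i), stringsAsFactors = FALSE)
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  q <- load_parameter_set(path)
  expect_equal(names(q$indications), names(p$indications))
  expect_equal(q$indications$ind02$median_os_tx,
               p$indications$ind02$median_os_tx)
  # missing column is a format error
  write.csv(df[, setdiff(names(df), "median_ttd")], path, row.names = FALSE)
  expect_error(load_parameter_set(path), "median_ttd")
})

test_that("PFS above OS is clamped with a warning; hard violations error", {
  ind <- simple_indication(median_pfs_tx = 30, median_os_tx = 20)
  expect_warning(p <- parameter_set(list(ind), fast_globals()),
                 "clamped")
  expect_equal(p$indications[[1]]$median_pfs_tx, 20)
  expect_length(attr(p, "clamp_log"), 1)

  expect_error(
    parameter_set(list(simple_indication(cost_pd_care = -5)), fast_globals()),
    "cost_pd_care")
  expect_error(
    parameter_set(list(simple_indication(weight = 0.5),
                       simple_indication(name = "beta", weight = 0.4)),
                  fast_globals()),
    "prevalence_weight")
  expect_error(
    parameter_set(list(simple_indication(median_os_soc = 0)), fast_globals()),
    "median_os_soc")
  expect_error(
    parameter_set(list(simple_indication(ntrk_prevalence = 0)),
                  fast_globals()),
    "ntrk_prevalence")
  expect_error(
    parameter_set(list(simple_indication(), simple_indication()),
                  fast_globals()),
    "unique")
  expect_error(
    parameter_set(list(simple_indication()),
                  global_params(utility_pf = 0.5, utility_pd = 0.7)),
    "utility")
})

test_that("two equal-weight indications are accepted", {
  p <- parameter_set(list(simple_indication(name = "a", weight = 0.5),
                          simple_indication(name = "b", weight = 0.5)),
                     fast_globals())
  expect_s3_class(p, "parameter_set")
})

test_that("fixture generation is seed-deterministic and valid", {
  a <- generate_fixture(seed = 7, n_indications = 3)
  b <- generate_fixture(seed = 7, n_indications = 3)
  expect_identical(a, b)
  c <- generate_fixture(seed = 8, n_indications = 3)
  expect_false(identical(
    sapply(a$indications, function(i) i$median_os_tx),
    sapply(c$indications, function(i) i$median_os_tx)))
  for (s in c(1, 2, 99)) {
    p <- generate_fixture(seed = s, n_indications = 5)
    w <- sapply(p$indications, function(i) i$prevalence_weight)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_length(attr(p, "clamp_log"), 0)  # valid with zero clamps
  }
})

test_that("small-sample rule flags trial_n <= 5 and zeroes incremental QALYs", {
  p <- parameter_set(
    list(simple_indication(name = "tiny", weight = 0.5, trial_n = 5),
         simple_indication(name = "big", weight = 0.5, trial_n = 6)),
    fast_globals())
  p <- apply_small_sample_rule(p)
  expect_true(p$indications$tiny$small_sample)
  expect_false(p$indications$big$small_sample)

  det <- run_deterministic(p)
  expect_identical(det$per_indication$delta_qaly[
    det$per_indication$name == "tiny"], 0)
  expect_gt(det$per_indication$delta_qaly[
    det$per_indication$name == "big"], 0)
})

test_that("indication subsetting renormalizes prevalence weights", {
  p <- generate_fixture(seed = 5, n_indications = 4)
  q <- select_indications(p, c("ind01", "ind03"))
  w <- sapply(q$indications, function(i) i$prevalence_weight)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  w0 <- sapply(p$indications[c("ind01", "ind03")],
               function(i) i$prevalence_weight)
  expect_equal(unname(w), unname(w0 / sum(w0)), tolerance = 1e-12)
  # distributions follow the subset
  pre <- sapply(strsplit(names(q$distributions), ".", fixed = TRUE), `[`, 1)
  expect_true(all(pre %in% c("global", "ind01", "ind03")))
})

test_that("distribution specs validate family parameters", {
  expect_s3_class(distribution_spec("gamma", list(mean = 10, cv = 0.2)),
                  "distribution_spec")
  expect_error(distribution_spec("beta", list(shape1 = -1, shape2 = 2)),
               "invalid")
  expect_error(distribution_spec("lognormal", list(mean = -3, cv = 0.2)),
               "invalid")
  expect_error(distribution_spec("weibull"), "arg")
  # unknown parameter names in the distributions map are rejected
  p <- simple_set()
  p$distributions[["ind1.not_a_field"]] <- distribution_spec("fixed")
  expect_error(validate_parameter_set(p), "not_a_field")
})

test_that("months are converted on load when the file declares them", {
  p <- generate_fixture(seed = 2, n_indications = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_parameter_set(p, path)
  raw <- yaml::read_yaml(path)
  raw$time_unit <- "months"
  for (i in seq_along(raw$indications)) {
    for (f in c("median_os_tx", "median_pfs_tx", "median_os_soc",
                "median_pfs_soc", "median_ttd")) {
      raw$indications[[i]][[f]] <- raw$indications[[i]][[f]] / 4.348125
    }
  }
  raw$distributions <- NULL
  yaml::write_yaml(raw, path, precision = 15)
  q <- load_parameter_set(path)
  expect_equal(q$indications$ind01$median_os_tx,
               p$indications$ind01$median_os_tx, tolerance = 1e-9)
})
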