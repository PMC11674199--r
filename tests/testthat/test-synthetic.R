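test_that("generate_roster is deterministic and honours degenerate probabilities", {
  p <- condition_sim_params(
    "GBS_FISHER", 50,
    criterion_prevalence = c(bilateral_weakness = 1, alt_dx_absent = 0),
    age_median = 26, age_min = 15, age_max = 58)
  r1 <- generate_roster(list(p), seed = 7)
  r2 <- generate_roster(list(p), seed = 7)
  expect_identical(r1, r2)
  expect_false(identical(r1, generate_roster(list(p), seed = 8)))
  expect_true(all(r1$`crit.bilateral_weakness` == "present"))
  expect_true(all(r1$`crit.alt_dx_absent` == "absent"))
  expect_true(all(r1$age >= 15 & r1$age <= 58))
})

test_that("per-condition streams are independent of list order and company", {
  params <- default_sim_params()
  full <- generate_roster(params, seed = 11)
  gbs_only <- generate_roster(
    Filter(function(p) p$condition == "GBS_FISHER", params), seed = 11)
  sub <- full[full$condition == "GBS_FISHER",
              intersect(names(full), names(gbs_only))]
  rownames(sub) <- NULL
  expect_identical(sub, gbs_only[, names(sub)])
  # n = 0 conditions are absent from the output
  expect_false("ANAPHYLAXIS" %in% full$condition)
})

test_that("empirical prevalence and missingness recover the parameters", {
  n <- 10000
  p <- condition_sim_params(
    "GBS_FISHER", n,
    criterion_prevalence = c(electrophys_consistent = 0.88,
                             dtr_decreased_in_weak_limbs = 0.5),
    criterion_missingness = c(electrophys_consistent = 0.27),
    age_median = 26, age_min = 15, age_max = 58)
  r <- generate_roster(list(p), seed = 19)
  ep <- r$`crit.electrophys_consistent`
  miss_hat <- mean(ep == "unknown")
  expect_lt(abs(miss_hat - 0.27), 3 * sqrt(0.27 * 0.73 / n))
  known <- ep[ep != "unknown"]
  prev_hat <- mean(known == "present")
  expect_lt(abs(prev_hat - 0.88),
            3 * sqrt(0.88 * 0.12 / length(known)))
  expect_lt(abs(stats::median(r$age) - 26), 2)
  expect_equal(range(r$age), c(15, 58))
})

test_that("invalid parameters are contract errors", {
  expect_error(condition_sim_params("GBS_FISHER", 5,
                                    criterion_prevalence = c(a = 1.2),
                                    age_median = 26, age_min = 15,
                                    age_max = 58),
               "probabilities")
  expect_error(condition_sim_params("GBS_FISHER", 5, age_median = 10,
                                    age_min = 15, age_max = 58),
               "age_min")
})

test_that("sim-params JSON round-trips and validates", {
  params <- default_sim_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_params(params, path)
  back <- load_sim_params(path)
  expect_equal(back, params)
  # the shipped default parameter file matches the in-code defaults
  shipped <- system.file("extdata", "sim_params.json", package = "aesiloc")
  expect_equal(load_sim_params(shipped), params)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_sim_params(bad), "not valid JSON")
})

test_that("the 203-case fixture matches the surveillance marginals", {
  r <- fixture_roster()
  expect_equal(nrow(r), 203)
  counts <- table(r$condition)
  expect_equal(counts[["THROMBOSIS_THROMBOEMBOLISM"]], 100)
  expect_equal(counts[["GENERALIZED_CONVULSION"]], 38)
  expect_equal(counts[["THROMBOCYTOPENIA"]], 23)
  expect_equal(counts[["GBS_FISHER"]], 11)
  expect_equal(counts[["MYOCARDITIS"]], 12)
  expect_equal(counts[["PERICARDITIS"]], 12)
  expect_equal(counts[["ENCEPHALITIS"]], 2)
  expect_equal(counts[["MYELITIS"]], 2)
  expect_equal(counts[["ADEM"]], 2)
  expect_equal(counts[["BELLS_PALSY"]], 1)
  expect_equal(sum(r$sex == "FEMALE"), 119)
  expect_equal(sum(r$detection_site == "EOPD"), 162)
  expect_equal(sum(r$residence == "ADDIS_ABABA"), 117)
  # GBS sub-roster criterion marginals (n present / N known)
  gbs <- r[r$condition == "GBS_FISHER", ]
  marg <- function(col) {
    v <- gbs[[paste0("crit.", col)]]
    c(sum(v == "present"), sum(v != "unknown"))
  }
  expect_equal(marg("bilateral_weakness"), c(11, 11))
  expect_equal(marg("dtr_decreased_in_weak_limbs"), c(10, 11))
  expect_equal(marg("onset_nadir_12h_28d"), c(11, 11))
  expect_equal(marg("electrophys_consistent"), c(7, 8))
  expect_equal(marg("csf_wbc_lt50"), c(1, 1))
  expect_equal(marg("csf_protein_elevated"), c(1, 1))
  expect_equal(marg("alt_dx_absent"), c(10, 11))
  # per-condition ages reproduce the stated medians and ranges
  demo <- demographics_table(r)
  gbs_row <- demo[demo$condition == "GBS_FISHER", ]
  expect_equal(c(gbs_row$age_median, gbs_row$age_min, gbs_row$age_max),
               c(26, 15, 58))
  thr_row <- demo[demo$condition == "THROMBOSIS_THROMBOEMBOLISM", ]
  expect_equal(c(thr_row$age_median, thr_row$age_min, thr_row$age_max),
               c(49, 16, 88))
})

test_that("classifying the fixture yields the published level bookkeeping", {
  cl <- classify_roster(fixture_roster())
  by_level <- table(factor(cl$loc, levels = 1:5))
  expect_equal(sum(by_level[1:3]), 187)
  expect_equal(by_level[["4"]], 7)
  expect_equal(by_level[["5"]], 9)
  confirmed <- function(cc) {
    sub <- cl[cl$condition == cc, ]
    sum(sub$loc %in% 1:3)
  }
  expect_equal(confirmed("THROMBOCYTOPENIA"), 23)
  expect_equal(confirmed("THROMBOSIS_THROMBOEMBOLISM"), 98)
  expect_equal(confirmed("GENERALIZED_CONVULSION"), 37)
  expect_equal(confirmed("GBS_FISHER"), 10)
  expect_equal(confirmed("MYOCARDITIS"), 10)
  expect_equal(confirmed("PERICARDITIS"), 9)
  # GBS: no level 1, level 2 modal
  gbs <- cl[cl$condition == "GBS_FISHER", ]
  expect_equal(sum(gbs$loc == 1), 0)
  expect_equal(unname(which.max(table(factor(gbs$loc, levels = 1:5)))), 2L)
})
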