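test_that("percentage convention: round half up, em-dash when undefined", {
  expect_equal(pct_int(7, 8), 88L)       # 87.5 rounds up
  expect_equal(pct_int(1, 8), 13L)       # 12.5 rounds up
  expect_equal(pct_int(187, 203), 92L)
  expect_equal(pct_int(196, 203), 97L)   # 96.55
  expect_true(is.na(pct_int(0, 0)))
  expect_equal(aesiloc:::fmt_n_pct(0, 0), "0/0 (—)")
  # even-sized median: mean of central pair, rounded half up
  expect_equal(aesiloc:::median_int(c(21L, 26L)), 24L)
})

test_that("summarize_loc reproduces the fixture distribution", {
  cl <- classify_roster(fixture_roster())
  s <- summarize_loc(cl)
  tot <- s[s$condition == "TOTAL", ]
  expect_equal(tot$confirmed_n, 187)
  expect_equal(tot$confirmed_pct, 92L)
  expect_equal(tot$classifiable_n, 196)
  expect_equal(tot$classifiable_pct, 97L)
  gbs <- s[s$condition == "GBS_FISHER", ]
  expect_equal(gbs$confirmed_pct, 91L)
  expect_equal(gbs$l1, 0)
  per_cond <- s[s$condition != "TOTAL", ]
  # per-condition level counts sum to the condition's case count
  expect_equal(per_cond$l1 + per_cond$l2 + per_cond$l3 + per_cond$l4 +
                 per_cond$l5, per_cond$n)
  # percent columns always recompute from the counts (no drift)
  expect_equal(tot$confirmed_pct, pct_int(tot$confirmed_n, tot$n))
  expect_equal(per_cond$l4_pct, pct_int(per_cond$l4, per_cond$n))
  # permutation invariance
  set.seed(5)
  expect_equal(summarize_loc(cl[sample(nrow(cl)), ]), s)
  # degenerate roster
  one <- cl[cl$loc == 5, ][1, ]
  s1 <- summarize_loc(one)
  expect_equal(s1[s1$condition == "TOTAL", ]$l5_pct, 100L)
  expect_equal(s1[s1$condition == "TOTAL", ]$confirmed_pct, 0L)
  expect_error(summarize_loc(fixture_roster()), "classify_roster")
})

test_that("rounding slack: confirmed + level-4 + level-5 percents ~ 100", {
  set.seed(33)
  cl <- classify_roster(generate_roster(default_sim_params(), seed = 23))
  s <- summarize_loc(cl)
  tot <- s[s$condition == "TOTAL", ]
  total_pct <- tot$confirmed_pct + tot$l4_pct + tot$l5_pct
  expect_lte(abs(total_pct - 100), 1)
})

test_that("tabulate_level4_reasons matches the narratives", {
  cl <- classify_roster(fixture_roster())
  reasons <- tabulate_level4_reasons(cl)
  expect_setequal(names(reasons),
                  c("PERICARDITIS", "ENCEPHALITIS", "MYELITIS",
                    "GENERALIZED_CONVULSION"))
  expect_equal(reasons$PERICARDITIS$count, 2)
  expect_true(all(c("ecg_typical", "chest_radiograph_suggestive") %in%
                    reasons$PERICARDITIS$reasons))
  expect_equal(reasons$ENCEPHALITIS$count, 2)
  expect_equal(reasons$MYELITIS$count, 2)
  expect_equal(reasons$GENERALIZED_CONVULSION$reasons, "bilateral_motor")
  # a roster with no unknowns has no level-4 cases to tabulate
  full <- cl[cl$loc != 4, ]
  expect_length(tabulate_level4_reasons(full), 0)
})

test_that("criterion_prevalence follows the n/N convention", {
  r <- fixture_roster()
  tab <- criterion_prevalence(r, "GBS_FISHER")
  row <- function(id) tab[tab$id == id, ]
  expect_equal(row("electrophys_consistent")$display, "7/8 (88)")
  expect_equal(row("alt_dx_absent")$display, "10/11 (91)")
  expect_equal(row("csf_wbc_lt50")$display, "1/1 (100)")
  expect_true(all(tab$n <= tab$N & tab$N <= 11))
  expect_equal(row("onset_nadir_12h_28d")$category, "TEMPORAL")
  # all-unknown condition: 0/0 with undefined percent rendered as em-dash
  enc <- criterion_prevalence(r, "ENCEPHALITIS")
  fever <- enc[enc$id == "fever", ]
  expect_equal(fever$display, "0/0 (—)")
  expect_true(is.na(fever$percent))
  expect_error(criterion_prevalence(r, "ANAPHYLAXIS"), "no cases")
})

test_that("demographics_table reproduces the fixture marginals", {
  d <- demographics_table(fixture_roster())
  tot <- d[d$condition == "TOTAL", ]
  expect_equal(c(tot$eopd_n, tot$ipd_n, tot$total_n), c(162, 41, 203))
  expect_equal(c(tot$male_n, tot$male_pct), c(84, 41))
  expect_equal(c(tot$addis_n, tot$addis_pct), c(117, 58))
  thr <- d[d$condition == "THROMBOSIS_THROMBOEMBOLISM", ]
  expect_equal(thr$total_pct, 49L)
  expect_equal(thr$eopd_n + thr$ipd_n, thr$total_n)
  # single-case roster: median equals the age, range collapses
  one <- fixture_roster()[3, ]
  d1 <- demographics_table(one)
  expect_equal(d1$age_median[1], one$age)
  expect_equal(d1$age_min[1], d1$age_max[1])
})

test_that("render_table emits both formats", {
  d <- demographics_table(fixture_roster())
  md <- render_table(d, "markdown")
  expect_match(md[2], "^\\|[-|]+\\|$")
  expect_length(md, nrow(d) + 2)
  csv <- render_table(d, "csv")
  parsed <- utils::read.csv(text = csv, check.names = FALSE)
  expect_equal(nrow(parsed), nrow(d))
})
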