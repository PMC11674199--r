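test_that("Kleene connectives behave on the defining cases", {
  a_u <- c(a = "present", b = "unknown")
  expect_true(is.na(eval_expr(all_of("a", "b"), a_u)))
  expect_true(eval_expr(any_of("a", "b"), a_u))
  expect_true(is.na(eval_expr(not_of("b"), a_u)))
  expect_false(eval_expr(all_of("a", "b"),
                         c(a = "present", b = "absent")))
  # threshold: 1 present, could reach 2 only via the unknown
  expect_true(is.na(eval_expr(
    at_least(2, "a", "b", "c"),
    c(a = "present", b = "absent", c = "unknown"))))
  expect_true(eval_expr(at_least(2, "a", "b", "c"),
                        c(a = "present", b = "present", c = "unknown")))
  expect_false(eval_expr(at_least(2, "a", "b", "c"),
                         c(a = "present", b = "absent", c = "absent")))
  # missing entries read unknown
  expect_true(is.na(eval_expr(atom("zzz"), c(a = "present"))))
  # known incompleteness of Kleene logic, accepted: a OR NOT a with a
  # unknown is unknown even though every completion is true
  expect_true(is.na(eval_expr(any_of("a", not_of("a")), c(a = "unknown"))))
})

test_that("Kleene evaluation is sound against every two-valued completion", {
  set.seed(101)
  atoms <- letters[1:6]
  for (i in 1:400) {
    e <- random_expr(atoms)
    asg <- random_assignment(expr_atoms(e))
    res <- eval_expr(e, asg)
    comp <- vapply(completions(asg), function(b) eval2(e, b), logical(1))
    if (isTRUE(res)) expect_true(all(comp))
    else if (isFALSE(res)) expect_false(any(comp))
    # with no unknowns, three-valued equals two-valued evaluation
    if (!any(asg == "unknown")) expect_equal(res, comp[[1]])
  }
})

test_that("classify_case reproduces the GBS level-1/2 logic", {
  rules <- gbs_rule_set()
  # electrophysiology consistent (AMAN), CSF untested: level 2
  lvl2 <- gbs_case("G1", gbs_core_present(),
                   electrophys_consistent = "present")
  res <- classify_case(lvl2, rules)
  expect_equal(res$level, 2L)
  expect_equal(res$satisfied_level, 2L)
  expect_length(res$blocking_unknowns, 0)
  # adding cytoalbuminologic dissociation lifts it to level 1
  lvl1 <- gbs_case("G2", gbs_core_present(),
                   electrophys_consistent = "present",
                   csf_wbc_lt50 = "present", csf_protein_elevated = "present")
  expect_equal(classify_case(lvl1, rules)$level, 1L)
  # the temporal criterion derives from onset-to-nadir hours
  lvl2b <- case_record("G3", "GBS_FISHER", 26, "FEMALE", "ADDIS_ABABA",
                       "IPD",
                       criteria = c(gbs_core_present()[-4],
                                    electrophys_consistent = "present"),
                       onset_to_nadir_hours = 480)
  expect_equal(classify_case(lvl2b, rules)$level, 2L)
  # condition mismatch is a contract error
  expect_error(classify_case(lvl2, load_rule_sets()[["MYOCARDITIS"]]),
               "condition mismatch")
})

test_that("level 4 arises only from unknowns and is explained by them", {
  rules <- load_rule_sets()
  # pericarditis with one suggestive sign and untested ECG / radiograph /
  # effusion: level 4 blocked by those unknowns
  peri <- case_record("P1", "PERICARDITIS", 29, "MALE", "OUTSIDE", "IPD",
                      criteria = c(typical_chest_pain = "present",
                                   pericardial_rub = "absent"))
  res <- classify_case(peri, rules$PERICARDITIS)
  expect_equal(res$level, 4L)
  expect_true(all(c("ecg_typical", "chest_radiograph_suggestive") %in%
                    res$blocking_unknowns))
  expect_setequal(explain_level4(peri, rules$PERICARDITIS),
                  res$blocking_unknowns)
  # resolving every blocking unknown forces a definite level
  grid <- expand.grid(rep(list(c("present", "absent")),
                          length(res$blocking_unknowns)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    resolved <- peri
    fill <- unlist(grid[i, ])
    names(fill) <- res$blocking_unknowns
    resolved$criteria <- c(resolved$criteria, fill)
    expect_true(classify_case(resolved, rules$PERICARDITIS)$level %in%
                  c(1L, 2L, 3L, 5L))
  }
  # explain_level4 is a contract error on a classifiable case
  expect_error(explain_level4(gbs_case("G1", gbs_core_present(),
                                       electrophys_consistent = "present"),
                              rules$GBS_FISHER),
               "not level 4")
})

test_that("level 5 means the most sensitive predicate is definitively false", {
  rules <- gbs_rule_set()
  ids <- expr_atoms(rules$level3)
  all_absent <- stats::setNames(rep("absent", length(ids)), ids)
  res <- classify_case(gbs_case("G5", all_absent), rules)
  expect_equal(res$level, 5L)
  expect_gt(length(res$failed_criteria), 0)
  expect_length(res$blocking_unknowns, 0)
  # a single definitive exclusion criterion suffices
  res2 <- classify_case(gbs_case("G6", gbs_core_present()["bilateral_weakness"],
                                 alt_dx_absent = "absent"), rules)
  expect_equal(res2$level, 5L)
  expect_true("alt_dx_absent" %in% res2$failed_criteria)
})

test_that("properties: no-unknowns totality, level order, monotone confirmation", {
  set.seed(202)
  rules <- load_rule_sets()
  conds <- c("GBS_FISHER", "PERICARDITIS", "MYOCARDITIS", "ENCEPHALITIS",
             "GENERALIZED_CONVULSION", "THROMBOSIS_THROMBOEMBOLISM")
  for (i in 1:200) {
    cond <- sample(conds, 1)
    rs <- rules[[cond]]
    ids <- vapply(rs$criteria, `[[`, "", "id")
    # fully-known assignment: never level 4, and the level is the
    # minimum k whose predicate is true (independent re-evaluation)
    known <- stats::setNames(sample(c("present", "absent"), length(ids),
                                    replace = TRUE), ids)
    case <- case_record("PK", cond, 30, "MALE", "OUTSIDE", "EOPD",
                        criteria = known)
    res <- classify_case(case, rs)
    expect_false(res$level == 4L)
    truths <- vapply(1:3, function(k) {
      isTRUE(eval_expr(rs[[paste0("level", k)]], known))
    }, logical(1))
    expect_equal(res$level,
                 if (any(truths)) which(truths)[1] else 5L)
    # monotone confirmation: resolving an unknown criterion that does
    # not appear in the satisfied predicate leaves the level unchanged
    tri <- random_assignment(ids)
    case2 <- case_record("PM", cond, 30, "MALE", "OUTSIDE", "EOPD",
                         criteria = tri[tri != "unknown"])
    res2 <- classify_case(case2, rs)
    if (res2$level %in% 1:3) {
      sat_atoms <- expr_atoms(rs[[paste0("level", res2$satisfied_level)]])
      outside <- setdiff(names(tri)[tri == "unknown"], sat_atoms)
      for (id in outside) {
        for (v in c("present", "absent")) {
          bumped <- tri
          bumped[id] <- v
          case3 <- case_record("PM2", cond, 30, "MALE", "OUTSIDE", "EOPD",
                               criteria = bumped[bumped != "unknown"])
          lvl3 <- classify_case(case3, rs)$level
          # the satisfied predicate is untouched, so certainty can only
          # improve; a level-1 result cannot change at all
          expect_lte(lvl3, res2$level)
          if (res2$level == 1L) expect_equal(lvl3, 1L)
        }
      }
    }
  }
})
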