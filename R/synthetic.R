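#' Simulation parameters for one condition
#'
#' Describes the statistical structure of one condition's sub-roster in a
#' synthetic hospital AESI surveillance: how many cases, the probability
#' each criterion is truly present among genuine cases, the probability a
#' criterion value is missing (masked to unknown, overriding the drawn
#' value), the fraction of not-a-case records (generated by forcing the
#' condition's key exclusion criteria, `not_a_case_overrides`), the age
#' distribution (integer years, matched by minimum / median / maximum)
#' and the demographic splits.
#'
#' @param condition one of [condition_codes()].
#' @param n_cases number of cases to generate (0 allowed: condition
#'   absent from the output).
#' @param criterion_prevalence named numeric vector, probability in
#'   `[0,1]` that each criterion is present among true cases.
#' @param criterion_missingness named numeric vector, probability in
#'   `[0,1]` that each criterion is masked to unknown.
#' @param prop_not_a_case probability a record is generated as
#'   definitively excluded.
#' @param not_a_case_overrides named character vector of tri-state values
#'   applied to excluded records (e.g. `c(alt_dx_absent = "absent")`).
#' @param age_median,age_min,age_max integer years,
#'   `age_min <= age_median <= age_max`.
#' @param prop_male,prop_addis,prop_eopd probabilities of male sex,
#'   Addis Ababa residence, and detection at the emergency outpatient
#'   department.
#' @return a `condition_sim_params` object.
#' @export
condition_sim_params <- function(condition, n_cases,
                                 criterion_prevalence = numeric(),
                                 criterion_missingness = numeric(),
                                 prop_not_a_case = 0,
                                 not_a_case_overrides = character(),
                                 age_median, age_min, age_max,
                                 prop_male = 0.5, prop_addis = 0.5,
                                 prop_eopd = 0.5) {
  condition <- match.arg(condition, condition_codes())
  n_cases <- as.integer(n_cases)
  stopifnot(n_cases >= 0L)
  probs <- c(criterion_prevalence, criterion_missingness, prop_not_a_case,
             prop_male, prop_addis, prop_eopd)
  if (any(probs < 0 | probs > 1)) {
    stop(condition, ": probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!(age_min <= age_median && age_median <= age_max)) {
    stop(condition, ": need age_min <= age_median <= age_max",
         call. = FALSE)
  }
  if (length(not_a_case_overrides)) {
    assert_tri(not_a_case_overrides, "not_a_case_overrides")
  }
  structure(list(condition = condition, n_cases = n_cases,
                 criterion_prevalence = criterion_prevalence,
                 criterion_missingness = criterion_missingness,
                 prop_not_a_case = prop_not_a_case,
                 not_a_case_overrides = not_a_case_overrides,
                 age_median = as.integer(age_median),
                 age_min = as.integer(age_min),
                 age_max = as.integer(age_max),
                 prop_male = prop_male, prop_addis = prop_addis,
                 prop_eopd = prop_eopd),
            class = "condition_sim_params")
}

round_half_up <- function(x) floor(x + 0.5)

# Ages matching stated min / median / max exactly: draw below or above
# the median with probability 1/2 each, uniformly within the half-range.
# (A triangular distribution cannot realize strongly skewed medians such
# as min 14 / median 31 / max 82 within the stated range.)
draw_ages <- function(n, age_min, age_median, age_max) {
  lower <- stats::runif(n) < 0.5
  out <- ifelse(lower,
                stats::runif(n, age_min, age_median),
                stats::runif(n, age_median, age_max))
  as.integer(round_half_up(out))
}

# Deterministic per-condition stream seed so that adding or reordering
# conditions does not perturb the draws of the others.
condition_stream_seed <- function(seed, condition) {
  h <- sum(utf8ToInt(condition) * seq_along(utf8ToInt(condition)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Generate a seeded synthetic surveillance roster
#'
#' For each condition, criteria are drawn independently per case: present
#' with the stated prevalence (else absent), then masked to unknown with
#' the stated missingness. A `prop_not_a_case` fraction of records is
#' generated as definitively excluded by applying
#' `not_a_case_overrides`. Ages are drawn to match the stated minimum,
#' median and maximum. One RNG stream per condition is derived from
#' `seed`, so rosters are reproducible and per-condition draws are
#' independent of the parameter list order.
#'
#' @param params list of [condition_sim_params()] objects.
#' @param seed single integer seed.
#' @return a roster data frame (see [read_linelist()] for the layout).
#' @export
generate_roster <- function(params, seed) {
  stopifnot(length(params) >= 1L)
  if (inherits(params, "condition_sim_params")) params <- list(params)
  stopifnot(all(vapply(params, inherits, TRUE, "condition_sim_params")))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  all_crit <- unique(unlist(lapply(params, function(p) {
    union(names(p$criterion_prevalence), names(p$criterion_missingness))
  }), use.names = FALSE))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  blocks <- list()
  for (p in params) {
    n <- p$n_cases
    if (n == 0L) next
    set.seed(condition_stream_seed(seed, p$condition))
    df <- data.frame(
      case_id = sprintf("SIM-%s-%04d", abbreviate_condition(p$condition),
                        seq_len(n)),
      condition = p$condition,
      age = draw_ages(n, p$age_min, p$age_median, p$age_max),
      sex = ifelse(stats::runif(n) < p$prop_male, "MALE", "FEMALE"),
      residence = ifelse(stats::runif(n) < p$prop_addis, "ADDIS_ABABA",
                         "OUTSIDE"),
      detection_site = ifelse(stats::runif(n) < p$prop_eopd, "EOPD", "IPD"),
      stringsAsFactors = FALSE)
    cond_crit <- union(names(p$criterion_prevalence),
                       names(p$criterion_missingness))
    crit <- matrix("unknown", nrow = n, ncol = length(all_crit),
                   dimnames = list(NULL, all_crit))
    for (id in cond_crit) {
      prev <- if (id %in% names(p$criterion_prevalence)) {
        p$criterion_prevalence[[id]]
      } else 0
      miss <- if (id %in% names(p$criterion_missingness)) {
        p$criterion_missingness[[id]]
      } else 0
      v <- ifelse(stats::runif(n) < prev, "present", "absent")
      v[stats::runif(n) < miss] <- "unknown"
      crit[, id] <- v
    }
    if (length(p$not_a_case_overrides)) {
      excluded <- stats::runif(n) < p$prop_not_a_case
      for (id in names(p$not_a_case_overrides)) {
        crit[excluded, id] <- p$not_a_case_overrides[[id]]
      }
    }
    colnames(crit) <- paste0("crit.", all_crit)
    blocks[[length(blocks) + 1L]] <-
      cbind(df, as.data.frame(crit, stringsAsFactors = FALSE))
  }
  if (length(blocks) == 0L) {
    stop("all conditions have n_cases = 0", call. = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  validate_roster(out)
}

abbreviate_condition <- function(code) {
  c(MYOCARDITIS = "MYO", PERICARDITIS = "PER",
    INJECTION_SITE_ABSCESS = "ABS", TTS = "TTS",
    THROMBOCYTOPENIA = "TCP", THROMBOSIS_THROMBOEMBOLISM = "THR",
    ANAPHYLAXIS = "ANA", ADEM = "ADE", BELLS_PALSY = "BEL",
    GENERALIZED_CONVULSION = "CON", GBS_FISHER = "GBS",
    ENCEPHALITIS = "ENC", MYELITIS = "MYE")[[code]]
}

#' Load simulation parameters from a JSON document
#'
#' The document is an array of objects mirroring the
#' [condition_sim_params()] fields; a default emulating a one-year
#' referral-hospital surveillance ships at
#' `system.file("extdata", "sim_params.json", package = "aesiloc")`.
#'
#' @param path JSON file path.
#' @return list of `condition_sim_params`.
#' @export
load_sim_params <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path,
                               call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("%s: not valid JSON (%s)", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!is.list(doc) || length(doc) == 0L) {
    stop(path, ": expected a non-empty array of parameter objects",
         call. = FALSE)
  }
  lapply(seq_along(doc), function(i) {
    d <- doc[[i]]
    tryCatch(
      condition_sim_params(
        condition = d$condition %||% stop("missing condition"),
        n_cases = d$n_cases %||% 0,
        criterion_prevalence = unlist(d$criterion_prevalence) %||% numeric(),
        criterion_missingness = unlist(d$criterion_missingness) %||% numeric(),
        prop_not_a_case = d$prop_not_a_case %||% 0,
        not_a_case_overrides = unlist(d$not_a_case_overrides) %||% character(),
        age_median = d$age_median, age_min = d$age_min, age_max = d$age_max,
        prop_male = d$prop_male %||% 0.5,
        prop_addis = d$prop_addis %||% 0.5,
        prop_eopd = d$prop_eopd %||% 0.5),
      error = function(e) {
        stop(sprintf("%s: entry %d: %s", path, i, conditionMessage(e)),
             call. = FALSE)
      })
  })
}

#' Write simulation parameters to JSON
#'
#' @param params list of `condition_sim_params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_params <- function(params, path) {
  doc <- lapply(params, function(p) {
    out <- unclass(p)
    out$criterion_prevalence <- as.list(out$criterion_prevalence)
    out$criterion_missingness <- as.list(out$criterion_missingness)
    out$not_a_case_overrides <- as.list(out$not_a_case_overrides)
    out
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Default simulation parameters
#'
#' One [condition_sim_params()] per surveillance condition, with counts,
#' demographics and criterion prevalence / missingness emulating a
#' one-year sentinel-hospital AESI roster of 203 cases (the same stated
#' world as [fixture_roster()]). Conditions with no detected cases
#' (injection-site abscess, TTS, anaphylaxis) carry `n_cases = 0`.
#'
#' @return list of `condition_sim_params`.
#' @export
default_sim_params <- function() {
  list(
    condition_sim_params(
      "THROMBOSIS_THROMBOEMBOLISM", 100,
      criterion_prevalence = c(imaging_confirmed = 0.85,
                               symptoms_at_site = 0.75,
                               clinical_diagnosis_documented = 0.98),
      criterion_missingness = c(imaging_confirmed = 0.13,
                                symptoms_at_site = 0.25),
      prop_not_a_case = 0.02,
      not_a_case_overrides = c(clinical_diagnosis_documented = "absent",
                               imaging_confirmed = "absent"),
      age_median = 49, age_min = 16, age_max = 88,
      prop_male = 0.32, prop_addis = 0.46, prop_eopd = 0.93),
    condition_sim_params(
      "GENERALIZED_CONVULSION", 38,
      criterion_prevalence = c(witnessed_seizure = 1,
                               bilateral_motor = 0.97,
                               loss_of_consciousness = 1,
                               tonic_and_clonic = 0.55,
                               postictal_state = 0.6),
      criterion_missingness = c(bilateral_motor = 0.03,
                                tonic_and_clonic = 0.2,
                                postictal_state = 0.3),
      age_median = 31, age_min = 14, age_max = 82,
      prop_male = 0.58, prop_addis = 0.9, prop_eopd = 0.92),
    condition_sim_params(
      "THROMBOCYTOPENIA", 23,
      criterion_prevalence = c(platelet_lt150 = 1,
                               repeat_count_confirmed = 0.4,
                               clinical_bleeding = 0.5),
      criterion_missingness = c(repeat_count_confirmed = 0.5,
                                clinical_bleeding = 0.2),
      age_median = 35, age_min = 13, age_max = 62,
      prop_male = 0.39, prop_addis = 0.57, prop_eopd = 0.91),
    condition_sim_params(
      "GBS_FISHER", 11,
      criterion_prevalence = c(bilateral_weakness = 1,
                               flaccid_weakness = 1,
                               dtr_decreased_in_weak_limbs = 0.95,
                               onset_nadir_12h_28d = 1,
                               alt_dx_absent = 1,
                               electrophys_consistent = 0.88,
                               csf_wbc_lt50 = 1,
                               csf_protein_elevated = 1),
      criterion_missingness = c(electrophys_consistent = 0.27,
                                csf_wbc_lt50 = 0.91,
                                csf_protein_elevated = 0.91),
      prop_not_a_case = 0.09,
      not_a_case_overrides = c(alt_dx_absent = "absent"),
      age_median = 26, age_min = 15, age_max = 58,
      prop_male = 0.36, prop_addis = 0.55, prop_eopd = 0.64),
    condition_sim_params(
      "MYOCARDITIS", 12,
      criterion_prevalence = c(compatible_symptoms = 0.85,
                               biomarker_elevated = 0.85,
                               echo_abnormal = 0.5, cmr_abnormal = 0.1,
                               ecg_abnormal = 0.6,
                               histopathology_myocardial_inflammation = 0.05),
      criterion_missingness = c(echo_abnormal = 0.4, cmr_abnormal = 0.85,
                                ecg_abnormal = 0.2,
                                histopathology_myocardial_inflammation = 0.9),
      prop_not_a_case = 0.17,
      not_a_case_overrides = c(
        compatible_symptoms = "absent", biomarker_elevated = "absent",
        histopathology_myocardial_inflammation = "absent"),
      age_median = 29, age_min = 17, age_max = 83,
      prop_male = 0.67, prop_addis = 0.5, prop_eopd = 0.08),
    condition_sim_params(
      "PERICARDITIS", 12,
      criterion_prevalence = c(typical_chest_pain = 0.9,
                               pericardial_rub = 0.35, ecg_typical = 0.6,
                               effusion_imaging = 0.5,
                               chest_radiograph_suggestive = 0.5,
                               histopathology = 0.02),
      criterion_missingness = c(ecg_typical = 0.2,
                                chest_radiograph_suggestive = 0.2,
                                effusion_imaging = 0.3,
                                histopathology = 0.95),
      prop_not_a_case = 0.08,
      not_a_case_overrides = c(
        typical_chest_pain = "absent", pericardial_rub = "absent",
        ecg_typical = "absent", effusion_imaging = "absent",
        chest_radiograph_suggestive = "absent", histopathology = "absent"),
      age_median = 29, age_min = 17, age_max = 83,
      prop_male = 0.67, prop_addis = 0.5, prop_eopd = 0.08),
    condition_sim_params(
      "ENCEPHALITIS", 2,
      criterion_prevalence = c(focal_cns_sign = 1, fever = 0.6,
                               csf_pleocytosis = 0.5, eeg_consistent = 0.5,
                               neuroimaging_consistent = 0.5),
      criterion_missingness = c(fever = 0.9, csf_pleocytosis = 0.9,
                                eeg_consistent = 0.9,
                                neuroimaging_consistent = 0.9),
      age_median = 24, age_min = 21, age_max = 26,
      prop_male = 0, prop_addis = 1, prop_eopd = 0.5),
    condition_sim_params(
      "MYELITIS", 2,
      criterion_prevalence = c(focal_cns_sign = 1, fever = 0.6,
                               csf_pleocytosis = 0.5, eeg_consistent = 0.5,
                               neuroimaging_consistent = 0.5),
      criterion_missingness = c(fever = 0.9, csf_pleocytosis = 0.9,
                                eeg_consistent = 0.9,
                                neuroimaging_consistent = 0.9),
      age_median = 24, age_min = 21, age_max = 26,
      prop_male = 0, prop_addis = 1, prop_eopd = 0.5),
    condition_sim_params(
      "ADEM", 2,
      criterion_prevalence = c(clinical_features = 1,
                               physician_diagnosis = 0.5,
                               supportive_test = 0.3, alt_dx_absent = 0.2),
      age_median = 24, age_min = 21, age_max = 26,
      prop_male = 0, prop_addis = 1, prop_eopd = 0.5),
    condition_sim_params(
      "BELLS_PALSY", 1,
      criterion_prevalence = c(clinical_features = 1,
                               physician_diagnosis = 0.5,
                               supportive_test = 0.3, alt_dx_absent = 0.2),
      age_median = 52, age_min = 52, age_max = 52,
      prop_male = 1, prop_addis = 0, prop_eopd = 1),
    condition_sim_params("INJECTION_SITE_ABSCESS", 0, age_median = 30,
                         age_min = 18, age_max = 60),
    condition_sim_params("TTS", 0, age_median = 30, age_min = 18,
                         age_max = 60),
    condition_sim_params("ANAPHYLAXIS", 0, age_median = 30, age_min = 18,
                         age_max = 60)
  )
}

# ---------------------------------------------------------------------------
# The hand-authored 203-case reference roster.

# Sorted integer ages hitting the stated minimum, median and maximum
# under the round-half-up median convention.
ages_with_median <- function(n, age_min, age_median, age_max) {
  if (n == 1L) return(age_median)
  if (n == 2L) return(c(age_min, age_max))
  if (n %% 2L == 0L) {
    c(round_half_up(seq(age_min, age_median, length.out = n / 2)),
      round_half_up(seq(age_median, age_max, length.out = n / 2)))
  } else {
    c(round_half_up(seq(age_min, age_median, length.out = (n + 1) / 2)),
      round_half_up(seq(age_median, age_max, length.out = (n + 1) / 2))[-1])
  }
}

#' The 203-case reference roster
#'
#' A deterministic, hand-authored roster emulating one year of
#' sentinel-hospital AESI surveillance (the study data themselves are not
#' shareable). Per-condition counts, detection-site, sex, residence and
#' age marginals match the published demographics table; criterion
#' patterns are the minimal assignments consistent with each condition's
#' confirmability narrative and the GBS criterion-prevalence table, with
#' untested criteria left unknown. Classifying it with the shipped rule
#' sets yields 187 cases at levels 1-3, 7 at level 4 and 9 at level 5.
#'
#' Highlights: all 23 thrombocytopenia and 98/100 thrombosis cases
#' confirm; 1/38 generalized convulsions is blocked by unknown bilateral
#' motor involvement; among the 11 GBS cases none reaches level 1 (the
#' single CSF-tested case lacks electrophysiology), level 2 is modal, and
#' one carries an alternative diagnosis (level 5); 2/12 pericarditis
#' cases are blocked by unknown ECG / chest radiograph / effusion
#' imaging; both encephalitis and both myelitis cases lack all CNS
#' inflammation indicators (level 4); 2 ADEM and 1 Bell's palsy case are
#' excluded (level 5).
#'
#' @return a roster data frame of 203 rows.
#' @export
fixture_roster <- function() {
  # demographics per condition: n, EOPD, male, Addis, age min/median/max
  demo <- list(
    ADEM = list(n = 2, eopd = 1, male = 0, addis = 2,
                age = c(21, 24, 26)),
    BELLS_PALSY = list(n = 1, eopd = 1, male = 1, addis = 0,
                       age = c(52, 52, 52)),
    ENCEPHALITIS = list(n = 2, eopd = 1, male = 0, addis = 2,
                        age = c(21, 24, 26)),
    GBS_FISHER = list(n = 11, eopd = 7, male = 4, addis = 6,
                      age = c(15, 26, 58)),
    GENERALIZED_CONVULSION = list(n = 38, eopd = 35, male = 22, addis = 34,
                                  age = c(14, 31, 82)),
    MYELITIS = list(n = 2, eopd = 1, male = 0, addis = 2,
                    age = c(21, 24, 26)),
    MYOCARDITIS = list(n = 12, eopd = 1, male = 8, addis = 6,
                       age = c(17, 29, 83)),
    PERICARDITIS = list(n = 12, eopd = 1, male = 8, addis = 6,
                        age = c(17, 29, 83)),
    THROMBOCYTOPENIA = list(n = 23, eopd = 21, male = 9, addis = 13,
                            age = c(13, 35, 62)),
    THROMBOSIS_THROMBOEMBOLISM = list(n = 100, eopd = 93, male = 32,
                                      addis = 46, age = c(16, 49, 88))
  )
  # criterion patterns: list of (count, named tri vector); unmentioned
  # criteria stay unknown
  pat <- function(k, ...) list(k = k, crit = c(...))
  patterns <- list(
    ADEM = list(
      pat(2, clinical_features = "present", alt_dx_absent = "absent")),
    BELLS_PALSY = list(
      pat(1, clinical_features = "present", alt_dx_absent = "absent")),
    ENCEPHALITIS = list(pat(2, focal_cns_sign = "present")),
    MYELITIS = list(pat(2, focal_cns_sign = "present")),
    GBS_FISHER = list(
      # the single CSF-tested case: dissociation present, no
      # electrophysiology -> level 2, never level 1
      pat(1, bilateral_weakness = "present", flaccid_weakness = "present",
          dtr_decreased_in_weak_limbs = "present",
          onset_nadir_12h_28d = "present", alt_dx_absent = "present",
          csf_wbc_lt50 = "present", csf_protein_elevated = "present"),
      # electrophysiology consistent, CSF untested -> level 2
      pat(7, bilateral_weakness = "present", flaccid_weakness = "present",
          dtr_decreased_in_weak_limbs = "present",
          onset_nadir_12h_28d = "present", alt_dx_absent = "present",
          electrophys_consistent = "present"),
      # clinical core only -> level 3
      pat(2, bilateral_weakness = "present", flaccid_weakness = "present",
          dtr_decreased_in_weak_limbs = "present",
          onset_nadir_12h_28d = "present", alt_dx_absent = "present"),
      # alternative diagnosis identified -> level 5 (also carries the
      # roster's single negative DTR and electrophysiology findings)
      pat(1, bilateral_weakness = "present", flaccid_weakness = "present",
          dtr_decreased_in_weak_limbs = "absent",
          onset_nadir_12h_28d = "present", alt_dx_absent = "absent",
          electrophys_consistent = "absent")),
    GENERALIZED_CONVULSION = list(
      pat(20, witnessed_seizure = "present", bilateral_motor = "present",
          loss_of_consciousness = "present", tonic_and_clonic = "present"),
      pat(10, witnessed_seizure = "present", bilateral_motor = "present",
          loss_of_consciousness = "present", tonic_and_clonic = "absent",
          postictal_state = "present"),
      pat(7, witnessed_seizure = "present", bilateral_motor = "present",
          loss_of_consciousness = "present"),
      # unknown whether movements involved both sides -> level 4
      pat(1, witnessed_seizure = "present",
          loss_of_consciousness = "present")),
    MYOCARDITIS = list(
      pat(2, compatible_symptoms = "present", biomarker_elevated = "present",
          echo_abnormal = "present"),
      pat(8, compatible_symptoms = "present",
          biomarker_elevated = "present"),
      pat(2, compatible_symptoms = "absent", biomarker_elevated = "absent",
          histopathology_myocardial_inflammation = "absent")),
    PERICARDITIS = list(
      pat(3, typical_chest_pain = "present", pericardial_rub = "present",
          ecg_typical = "present"),
      pat(6, typical_chest_pain = "present", pericardial_rub = "absent",
          ecg_typical = "absent", effusion_imaging = "absent",
          chest_radiograph_suggestive = "present",
          histopathology = "absent"),
      # unknown ECG, chest radiograph and effusion imaging -> level 4
      pat(2, typical_chest_pain = "present", pericardial_rub = "absent"),
      pat(1, typical_chest_pain = "absent", pericardial_rub = "absent",
          ecg_typical = "absent", effusion_imaging = "absent",
          chest_radiograph_suggestive = "absent",
          histopathology = "absent")),
    THROMBOCYTOPENIA = list(
      pat(23, platelet_lt150 = "present")),
    THROMBOSIS_THROMBOEMBOLISM = list(
      pat(60, imaging_confirmed = "present", symptoms_at_site = "present",
          clinical_diagnosis_documented = "present"),
      pat(25, imaging_confirmed = "present",
          clinical_diagnosis_documented = "present"),
      pat(13, clinical_diagnosis_documented = "present"),
      pat(2, imaging_confirmed = "absent", symptoms_at_site = "absent",
          clinical_diagnosis_documented = "absent"))
  )
  records <- list()
  idx <- 0L
  for (cond in names(demo)) {
    d <- demo[[cond]]
    stopifnot(sum(vapply(patterns[[cond]], `[[`, 0, "k")) == d$n)
    ages <- ages_with_median(d$n, d$age[1], d$age[2], d$age[3])
    crit_by_case <- unlist(lapply(patterns[[cond]], function(p) {
      rep(list(p$crit), p$k)
    }), recursive = FALSE)
    for (i in seq_len(d$n)) {
      idx <- idx + 1L
      records[[idx]] <- case_record(
        sprintf("AESI-%03d", idx), cond, ages[i],
        sex = if (i <= d$male) "MALE" else "FEMALE",
        residence = if (i <= d$addis) "ADDIS_ABABA" else "OUTSIDE",
        detection_site = if (i <= d$eopd) "EOPD" else "IPD",
        criteria = crit_by_case[[i]])
    }
  }
  records_to_roster(records)
}
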