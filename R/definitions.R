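#' Shipped case-definition rule sets
#'
#' The package ships one declarative rule set per surveillance condition
#' under `inst/definitions/<condition_code_lowercase>.json`. The
#' Guillain-Barre syndrome set follows the published case-definition logic
#' (see [gbs_rule_set()]); myocarditis, pericarditis, generalized
#' convulsion, encephalitis, myelitis, thrombocytopenia and
#' thrombosis/thromboembolism are simplified but internally nested,
#' tri-state-aware approximations; abscess, TTS, anaphylaxis, ADEM and
#' Bell's palsy are schema examples without validated clinical logic.
#' Every looser level predicate is written as the disjunction of the
#' stricter raw predicates, which guarantees the level-nesting invariant
#' by construction.
#'
#' @name definitions
NULL

#' Directory of the shipped rule-set files
#'
#' @return path to the installed `definitions/` directory.
#' @export
default_rules_dir <- function() {
  system.file("definitions", package = "aesiloc", mustWork = TRUE)
}

#' Load all rule sets from a directory
#'
#' Reads every `*.json` file in `dir` with [load_rule_set()].
#'
#' @param dir directory of rule-set JSON files; defaults to the shipped
#'   definitions.
#' @return named list of `rule_set` objects, keyed by condition code.
#' @export
load_rule_sets <- function(dir = default_rules_dir()) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  sets <- lapply(files, load_rule_set)
  names(sets) <- vapply(sets, `[[`, "", "condition")
  if (anyDuplicated(names(sets))) {
    stop("duplicate condition codes in ", dir, call. = FALSE)
  }
  sets
}

#' The Guillain-Barre syndrome rule set
#'
#' Level 3 (most sensitive) requires the clinical core: bilateral AND
#' flaccid limb weakness, decreased or absent deep-tendon reflexes in the
#' weak limbs, a monophasic course with onset-to-nadir between 12 hours
#' and 28 days, and absence of an identified alternative diagnosis.
#' Level 2 additionally requires either relative absence of CSF
#' pleocytosis (total white cell count < 50 cells/uL) or
#' electrophysiologic findings consistent with GBS (AIDP, AMAN and/or
#' AMSAN). Level 1 requires both cytoalbuminologic dissociation in CSF
#' (CSF WBC < 50 cells/uL with protein elevation) and the
#' electrophysiology criterion.
#'
#' @return a `rule_set` for condition `GBS_FISHER` with 8 criteria.
#' @export
gbs_rule_set <- function() {
  core <- list("bilateral_weakness", "flaccid_weakness",
               "dtr_decreased_in_weak_limbs", "onset_nadir_12h_28d",
               "alt_dx_absent")
  with_core <- function(...) do.call(all_of, c(core, list(...)))
  rule_set(
    condition = "GBS_FISHER",
    criteria = list(
      criterion_def("bilateral_weakness", "Bilateral weakness of limbs",
                    "CLINICAL"),
      criterion_def("flaccid_weakness", "Flaccid weakness of limbs",
                    "CLINICAL"),
      criterion_def("dtr_decreased_in_weak_limbs",
                    "Decreased or absent DTRs in weak limbs", "CLINICAL"),
      criterion_def("onset_nadir_12h_28d",
                    "Time between onset-nadir 12 h to 28 days", "TEMPORAL"),
      criterion_def("alt_dx_absent",
                    "Absence of identified alternative diagnosis for weakness",
                    "EXCLUSION"),
      criterion_def("electrophys_consistent",
                    "Electrophysiologic studies consistent with GBS (AIDP, AMAN and/or AMSAN)",
                    "ELECTROPHYSIOLOGY"),
      criterion_def("csf_wbc_lt50", "CSF WBC < 50 cells/uL", "LABORATORY"),
      criterion_def("csf_protein_elevated", "CSF protein elevation",
                    "LABORATORY")
    ),
    level1 = with_core("csf_wbc_lt50", "csf_protein_elevated",
                       "electrophys_consistent"),
    level2 = with_core(any_of("csf_wbc_lt50", "electrophys_consistent")),
    level3 = do.call(all_of, core),
    version = "aesiloc-1"
  )
}

# Builders for every shipped condition; the JSON files under
# inst/definitions/ are generated from these (tools/make_definitions.R)
# and the two forms are asserted identical in the test suite.
builtin_rule_set <- function(condition) {
  schema_example <- function(code) {
    rule_set(
      condition = code,
      criteria = list(
        criterion_def("clinical_features", "Compatible clinical features",
                      "CLINICAL"),
        criterion_def("physician_diagnosis",
                      "Physician diagnosis documented", "CLINICAL"),
        criterion_def("supportive_test", "Supportive diagnostic test",
                      "LABORATORY"),
        criterion_def("alt_dx_absent",
                      "Absence of identified alternative diagnosis",
                      "EXCLUSION")
      ),
      level1 = all_of("clinical_features", "physician_diagnosis",
                      "supportive_test", "alt_dx_absent"),
      level2 = all_of("clinical_features", "physician_diagnosis",
                      "alt_dx_absent"),
      level3 = all_of("clinical_features", "alt_dx_absent"),
      version = "aesiloc-1-schema-example"
    )
  }
  switch(condition,
    GBS_FISHER = gbs_rule_set(),
    MYOCARDITIS = {
      raw1 <- any_of("histopathology_myocardial_inflammation",
                     all_of("biomarker_elevated",
                            any_of("cmr_abnormal", "echo_abnormal")))
      raw2 <- all_of("biomarker_elevated", "compatible_symptoms")
      raw3 <- all_of("compatible_symptoms",
                     any_of("ecg_abnormal", "biomarker_elevated"))
      rule_set(
        condition = "MYOCARDITIS",
        criteria = list(
          criterion_def("histopathology_myocardial_inflammation",
                        "Histopathologic demonstration of myocardial inflammation",
                        "LABORATORY"),
          criterion_def("biomarker_elevated",
                        "Elevated myocardial biomarkers", "LABORATORY"),
          criterion_def("cmr_abnormal",
                        "Cardiac MR imaging abnormality", "IMAGING"),
          criterion_def("echo_abnormal",
                        "Echocardiographic abnormality", "IMAGING"),
          criterion_def("compatible_symptoms",
                        "Compatible cardiac symptoms", "CLINICAL"),
          criterion_def("ecg_abnormal", "ECG abnormality",
                        "ELECTROPHYSIOLOGY")
        ),
        level1 = raw1, level2 = any_of(raw1, raw2),
        level3 = any_of(raw1, raw2, raw3),
        version = "aesiloc-1"
      )
    },
    PERICARDITIS = {
      raw1 <- any_of("histopathology",
                     at_least(2, "typical_chest_pain", "pericardial_rub",
                              "ecg_typical", "effusion_imaging"))
      raw2 <- all_of(at_least(1, "typical_chest_pain", "pericardial_rub"),
                     at_least(1, "ecg_typical", "effusion_imaging",
                              "chest_radiograph_suggestive"))
      raw3 <- all_of("typical_chest_pain",
                     any_of("ecg_typical", "chest_radiograph_suggestive",
                            "effusion_imaging", "pericardial_rub"))
      rule_set(
        condition = "PERICARDITIS",
        criteria = list(
          criterion_def("typical_chest_pain",
                        "Typical pericarditic chest pain", "CLINICAL"),
          criterion_def("pericardial_rub", "Pericardial friction rub",
                        "CLINICAL"),
          criterion_def("ecg_typical", "Typical ECG changes",
                        "ELECTROPHYSIOLOGY"),
          criterion_def("effusion_imaging",
                        "Pericardial effusion on imaging", "IMAGING"),
          criterion_def("chest_radiograph_suggestive",
                        "Suggestive chest radiograph", "IMAGING"),
          criterion_def("histopathology",
                        "Histopathologic evidence of pericarditis",
                        "LABORATORY")
        ),
        level1 = raw1, level2 = any_of(raw1, raw2),
        level3 = any_of(raw1, raw2, raw3),
        version = "aesiloc-1"
      )
    },
    GENERALIZED_CONVULSION = rule_set(
      condition = "GENERALIZED_CONVULSION",
      criteria = list(
        criterion_def("witnessed_seizure",
                      "Witnessed sudden loss of consciousness with motor seizure",
                      "CLINICAL"),
        criterion_def("bilateral_motor",
                      "Motor involvement of both right and left limbs",
                      "CLINICAL"),
        criterion_def("loss_of_consciousness", "Loss of consciousness",
                      "CLINICAL"),
        criterion_def("tonic_and_clonic",
                      "Tonic and clonic motor manifestations", "CLINICAL"),
        criterion_def("postictal_state", "Post-ictal state documented",
                      "CLINICAL")
      ),
      level1 = all_of("witnessed_seizure", "bilateral_motor",
                      "loss_of_consciousness", "tonic_and_clonic"),
      level2 = all_of("witnessed_seizure", "bilateral_motor",
                      "loss_of_consciousness",
                      any_of("tonic_and_clonic", "postictal_state")),
      level3 = all_of("witnessed_seizure", "bilateral_motor",
                      "loss_of_consciousness"),
      version = "aesiloc-1"
    ),
    ENCEPHALITIS = ,
    MYELITIS = {
      indicators <- list("fever", "csf_pleocytosis", "eeg_consistent",
                         "neuroimaging_consistent")
      focal <- if (condition == "ENCEPHALITIS") {
        criterion_def("focal_cns_sign",
                      "Encephalopathy or focal CNS sign", "CLINICAL")
      } else {
        criterion_def("focal_cns_sign",
                      "Myelopathy: motor/sensory/autonomic spinal cord sign",
                      "CLINICAL")
      }
      raw1 <- all_of("focal_cns_sign",
                     any_of("histopathology",
                            all_of("neuroimaging_consistent",
                                   "csf_pleocytosis")))
      raw2 <- all_of("focal_cns_sign", at_least(2, indicators))
      raw3 <- all_of("focal_cns_sign", at_least(1, indicators))
      rule_set(
        condition = condition,
        criteria = list(
          focal,
          criterion_def("fever", "Fever (CNS inflammation indicator)",
                        "CLINICAL"),
          criterion_def("csf_pleocytosis", "CSF pleocytosis", "LABORATORY"),
          criterion_def("eeg_consistent", "EEG consistent with encephalopathy",
                        "ELECTROPHYSIOLOGY"),
          criterion_def("neuroimaging_consistent",
                        "Neuroimaging consistent with CNS inflammation",
                        "IMAGING"),
          criterion_def("histopathology",
                        "Histopathologic evidence of CNS inflammation",
                        "LABORATORY")
        ),
        level1 = raw1, level2 = any_of(raw1, raw2),
        level3 = any_of(raw1, raw2, raw3),
        version = "aesiloc-1"
      )
    },
    THROMBOCYTOPENIA = rule_set(
      condition = "THROMBOCYTOPENIA",
      criteria = list(
        criterion_def("platelet_lt150",
                      "Platelet count < 150 x 10^9/L", "LABORATORY"),
        criterion_def("repeat_count_confirmed",
                      "Confirmed on repeat platelet count", "LABORATORY"),
        criterion_def("clinical_bleeding",
                      "Clinical bleeding manifestations", "CLINICAL")
      ),
      level1 = all_of("platelet_lt150", "repeat_count_confirmed"),
      level2 = atom("platelet_lt150"),
      level3 = any_of("platelet_lt150", "clinical_bleeding"),
      version = "aesiloc-1"
    ),
    THROMBOSIS_THROMBOEMBOLISM = rule_set(
      condition = "THROMBOSIS_THROMBOEMBOLISM",
      criteria = list(
        criterion_def("imaging_confirmed",
                      "Site-specific imaging confirmation of thrombosis",
                      "IMAGING"),
        criterion_def("symptoms_at_site",
                      "Symptoms or signs at the thrombosis site", "CLINICAL"),
        criterion_def("clinical_diagnosis_documented",
                      "Documented clinical diagnosis of thrombosis/thromboembolism",
                      "CLINICAL")
      ),
      level1 = all_of("imaging_confirmed", "symptoms_at_site"),
      level2 = atom("imaging_confirmed"),
      level3 = any_of("imaging_confirmed", "clinical_diagnosis_documented"),
      version = "aesiloc-1"
    ),
    INJECTION_SITE_ABSCESS = ,
    TTS = ,
    ANAPHYLAXIS = ,
    ADEM = ,
    BELLS_PALSY = schema_example(condition),
    stop("no built-in rule set for condition ", condition, call. = FALSE)
  )
}

builtin_rule_sets <- function() {
  sets <- lapply(condition_codes(), builtin_rule_set)
  names(sets) <- condition_codes()
  sets
}
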