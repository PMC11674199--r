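# Regenerates inst/definitions/*.json and inst/extdata/sim_params.json
# from the in-code builders. Run from the package root:
#   Rscript tools/make_definitions.R
pkgload::load_all(".", quiet = TRUE)
dir.create("inst/definitions", recursive = TRUE, showWarnings = FALSE)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
for (code in condition_codes()) {
  write_rule_set(builtin_rule_set(code),
                 file.path("inst/definitions",
                           paste0(tolower(code), ".json")))
}
write_sim_params(default_sim_params(), "inst/extdata/sim_params.json")
cat("wrote", length(condition_codes()), "rule sets and sim_params.json\n")
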