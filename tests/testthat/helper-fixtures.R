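# Shared fixtures: the packaged tables load once per test file.
demo_tab <- load_fixture_table("demographics")
conc_tab <- load_fixture_table("concentrations")
crf_tab  <- load_fixture_table("cr_functions")
attr_tab <- load_fixture_table("attributed_outcomes")
stroke_tab <- load_fixture_table("stroke_strata")

# Tiny demographics for hand-computable cases.
demo1 <- function(time = 1, intake = 10, adaf = 1) {
  data.frame(label = "all", population_fraction = 1, adaf = adaf,
             time_at_home = time, intake_m3_day = intake)
}
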