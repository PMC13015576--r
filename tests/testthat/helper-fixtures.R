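# Shared fixtures and frozen oracle values.

os_pars <- function() weibull_params(1.473, 79.4)
ttp_pars <- function() weibull_params(1.560, 53.9)

# computed independently with 40-digit arithmetic before the build
ORACLE_P_DEATH_WK0 <- 0.00158934817873   # 1 - exp(-(1/79.4)^1.473)
ORACLE_MEDIAN_OS_WK <- 61.90974807       # 79.4 * log(2)^(1/1.473)
ORACLE_MEDIAN_TTP_WK <- 42.61414746      # 53.9 * log(2)^(1/1.560)

# a minimal two-strategy scenario for engine-level tests
toy_scenario <- function() {
  iri <- regimen_from_components("irinotecan_mono", "iri_mono",
                                 "admin_short", 3)
  sox <- regimen_from_components("sox", c("s1_combo", "oxaliplatin"),
                                 "admin_short", 3)
  scenario_spec(
    "toy",
    list(
      strategy_spec("stop", NULL, iri, rr_os = 1.5, rr_ttp = 1.5,
                    ae = adverse_event_profile()),
      strategy_spec("sox", sox, iri, rr_os = 0.93, rr_ttp = 1,
                    ae = ae_profile_s1(), s1_based = TRUE)
    ),
    reference_strategy = "stop"
  )
}

random_weibull <- function() {
  weibull_params(shape = runif(1, 0.8, 2.5), scale = runif(1, 20, 120))
}
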