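#!/usr/bin/env Rscript
# Fit the thermal melt and the chemical denaturation series written by
# 01_simulate_datasets.R, report the recovered thermodynamic parameters
# against the generating values, and write JSON result records.

suppressPackageStartupMessages(library(kowtherm))
dir.create("results", showWarnings = FALSE)

melt <- read_unfolding_table("results/data/melt_EcRfaH_CD_pH7.tsv")
fit_t <- fit_thermal_two_state(melt)
print(fit_t)
message(sprintf("  generating values: Tm = 50.30 degC, dHu(Tm) = 121 kJ/mol"))
message(sprintf("  recovered:         Tm = %.2f degC, dHu(Tm) = %.0f kJ/mol",
                kelvin_to_celsius(fit_t$params$Tm), fit_t$params$dH_Tm))

chem <- read_unfolding_table("results/data/urea_VcRfaH_pH7.tsv")
fit_c <- fit_chemical_lem(chem)
print(fit_c)
message(sprintf("  generating values: dGu(H2O) = 14.0 kJ/mol, m = 2.98 kJ/(mol M), midpoint = 4.70 M"))
message(sprintf("  recovered:         dGu(H2O) = %.2f kJ/mol, m = %.2f kJ/(mol M), midpoint = %.2f M",
                fit_c$params$dG_H2O, fit_c$params$m_value, fit_c$midpoint))

s139 <- read_unfolding_table("results/data/urea_S139_peakvolume.tsv")
fit_s <- fit_chemical_lem(s139)
print(fit_s)
message(sprintf("  peak-volume route: dG = %.2f kJ/mol, m = %.2f kJ/(mol M) (generated at 7 / 3.4)",
                fit_s$params$dG_H2O, fit_s$params$m_value))

write_result_json(list(
  result_record("thermal_two_state",
                c(Tm_K = fit_t$params$Tm, dH_Tm = fit_t$params$dH_Tm),
                se = fit_t$se[c("Tm", "dH_Tm")],
                diagnostics = list(flags = fit_t$flags), seed = 20260924),
  result_record("chemical_lem",
                c(dG_H2O = fit_c$params$dG_H2O,
                  m_value = fit_c$params$m_value,
                  midpoint_M = fit_c$midpoint),
                se = fit_c$se[c("dG_H2O", "m_value")],
                diagnostics = list(flags = fit_c$flags), seed = 20260925),
  result_record("chemical_lem_peak_volume",
                c(dG_H2O = fit_s$params$dG_H2O,
                  m_value = fit_s$params$m_value),
                se = fit_s$se[c("dG_H2O", "m_value")],
                diagnostics = list(flags = fit_s$flags), seed = 20260926)),
  "results/unfolding_fits.json")
message("written: results/unfolding_fits.json")
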