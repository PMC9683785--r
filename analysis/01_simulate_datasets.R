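#!/usr/bin/env Rscript
# Generate one synthetic dataset per measurement type at the library's
# study conditions and write them as the delimited dialects the fitters
# read. Downstream scripts (02-04) consume these files.

suppressPackageStartupMessages(library(kowtherm))

seed <- 20260924L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

message("Thermal CD melt (EcRfaH-KOW regime, Tm 50.3 degC) ...")
melt <- gen_scenario("EcRfaH_CD_pH7", seed = seed)
write_unfolding_table(melt, "results/data/melt_EcRfaH_CD_pH7.tsv")

message("Urea denaturation (VcRfaH-KOW regime, dG 14.0 kJ/mol) ...")
chem <- gen_scenario("VcRfaH_urea_pH7", seed = seed + 1L)
write_unfolding_table(chem, "results/data/urea_VcRfaH_pH7.tsv")

message("Peak-volume titration (S139-style, dG ~7 kJ/mol) ...")
s139 <- gen_scenario("S139_NMR_urea", seed = seed + 2L)
write_unfolding_table(s139, "results/data/urea_S139_peakvolume.tsv")

message("DSC thermogram (EcNusG-KOW regime, Tm 87.0 degC) ...")
tg <- gen_scenario("EcNusG_DSC_pH7", seed = seed + 3L)
write_thermogram_table(tg, "results/data/dsc_EcNusG_pH7.tsv")

message("Dual-B1 CEST profiles (EcRfaH-KOW regime, pB 5.53%) ...")
cest <- gen_scenario("EcRfaH_CEST", seed = seed + 4L)
write_cest_table(cest, "results/data/cest_EcRfaH.tsv")

message("Done. Files under results/data/ (seed ", seed, ").")
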