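id,recipe,expected,tolerance
chek2_mlpa_prevalence_pct,mlpa_prevalence_chek2,75.6,0
rb1_mlpa_prevalence_pct,mlpa_prevalence_rb1,9.8,0
brca2_mlpa_prevalence_pct,mlpa_prevalence_brca2,12.2,0
rb1_brca2_mlpa_codeletion_n,mlpa_codeletion_count,2,0
mlpa_cohort_n,mlpa_n_samples,41,0
chek2_ngs_prevalence_pct,ngs_prevalence_chek2,37.5,0
rb1_ngs_prevalence_pct,ngs_prevalence_rb1,25.0,0
brca2_ngs_prevalence_pct,ngs_prevalence_brca2,12.5,0
rb1_brca2_ngs_codeletion_pct,ngs_codeletion_pct,12.5,0
fisher_location_rb1_p,fisher_location_rb1,0.013,0.001
training_nih_low_very_low_n,training_nih_lowverylow_marginal,48,0
training_cohort_n,training_n,84,0
tma_cohort_n,tma_n,285,0
tma_kit_ex11_del_n,tma_kit_ex11_n,83,0
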