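hazard,outcome,incidence,incidence_lo,incidence_hi,rate_basis,daly,daly_lo,daly_hi
SHS,asthma_episodes,202300,,,national_count,0.040,,
SHS,otitis_media_visits,790000,,,national_count,0.022,,
SHS,sudden_infant_death_syndrome,430,,,national_count,78,,
SHS,cardiac_death,46000,22700,69600,national_count,1,,
SHS,lung_cancer_death,3400,,,national_count,14,,
radon_smoker,lung_cancer_death,18000,5600,58000,national_count,14,,
radon_nonsmoker,lung_cancer_death,3000,950,96000,national_count,14,,
acute_CO,poisoning_death,1.53,1.47,1.59,per_million_rate,32,,
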