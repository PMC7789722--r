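region,q_infant_per1000,q_child_per1000,cost_per_treatment_usd,incidence_per_child_year,baseline_coverage_pct,birth_cohort,reported_u5mr_per1000,urban_fraction
Afar,76.7,11.5,247.8,0.244,44,73000,125,
Beni-Shangul,60.2,9.2,271.3,0.102,29,34000,98,
Somali,50.5,4.3,271.3,0.119,32,305000,94,
Dire Dawa,16.4,1.7,124.8,0.221,50,10700,93,
Gambela,60.2,9.2,124.8,0.198,29,11300,88,
SNNP,64.9,7.0,288,0.385,43,621000,88,
Amhara,57.3,4.1,277.7,0.453,29,575000,85,
Oromia,56.6,3.9,281.6,0.419,26.4,1409000,79,
Harari,52.9,7.8,163.9,0.044,45,7500,72,
Tigray,57.8,5.6,255.1,0.436,34,178000,59,
Addis,30.0,5.0,45,0.153,59,45000,39,
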