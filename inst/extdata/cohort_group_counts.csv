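group,measure,criterion,value,pct
overall,n_total,,105261,100
african_american,n_total,,19258,18.3
japanese_american,n_total,,27227,25.9
latino,n_total,,21383,20.3
nhpi,n_total,,8368,7.9
white,n_total,,29025,27.6
overall,incident_cases_6yr,,1464,1.4
african_american,incident_cases_6yr,,432,2.2
japanese_american,incident_cases_6yr,,315,1.2
latino,incident_cases_6yr,,159,0.7
nhpi,incident_cases_6yr,,125,1.5
white,incident_cases_6yr,,433,1.5
overall,eligible,uspstf_2021,25282,24.0
african_american,eligible,uspstf_2021,4115,21.4
japanese_american,eligible,uspstf_2021,6932,25.5
latino,eligible,uspstf_2021,3360,15.7
nhpi,eligible,uspstf_2021,2104,25.1
white,eligible,uspstf_2021,8771,30.2
overall,eligible,uspstf_2013,15681,14.9
african_american,eligible,uspstf_2013,2486,12.9
japanese_american,eligible,uspstf_2013,4301,15.8
latino,eligible,uspstf_2013,2110,9.9
nhpi,eligible,uspstf_2013,1137,13.6
white,eligible,uspstf_2013,5647,19.5
overall,eligible,plco_update,25284,24.0
african_american,eligible,plco_update,6879,35.7
japanese_american,eligible,plco_update,5837,21.4
latino,eligible,plco_update,2549,11.9
nhpi,eligible,plco_update,2071,24.7
white,eligible,plco_update,7948,27.4
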