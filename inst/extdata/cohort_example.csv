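sex,birth_start,born_in_state,n_deaths,n_case_deaths
female,1900,TRUE,1000,30
female,1905,TRUE,2000,80
male,1900,TRUE,1500,30
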