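label,sex,birth_start,born_in_state,n_probands,observed
example constellation,female,1900,TRUE,100,9
example constellation,female,1905,TRUE,50,9
example constellation,male,1900,TRUE,200,9
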