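sex,lineage,count
female,paternal,37
female,maternal,67
male,paternal,25
male,maternal,46
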