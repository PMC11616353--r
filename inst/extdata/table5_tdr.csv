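sex,lineage,count
female,paternal,629
female,maternal,582
male,paternal,343
male,maternal,296
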