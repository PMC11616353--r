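{"label":"table4_sdr.csv","input":{"path":"inst/extdata/table4_sdr.csv","counts":{"a":37,"b":67,"c":25,"d":46},"total":175},"provenance":{"package":"XLinkRisk","version":"0.99.0","timestamp":"2026-09-27T12:04:44+0000","input":"inst/extdata/table4_sdr.csv","options":{"level":0.95,"correct":false}},"or":{"label":"table4_sdr.csv","counts":{"a":37,"b":67,"c":25,"d":46},"or_point":1.01611940298508,"log_or":0.0159908648741531,"se_log_or":0.322011693259947,"level":0.95,"ci_low":0.54056496410534,"ci_high":1.91003618377595,"z":0.0496592676876624,"p_two_sided":0.960393916063324,"x_proportion_pct":1.58636897767337,"flags":null}}
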