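label,observed,expected
>=1 maternal first cousin (female probands),582,523.37
>=1 paternal first cousin (female probands),629,553.3
>=1 mother's brother (female probands),25,17.04
>=1 father's brother (female probands),11,11.97
>=1 mother's sister (female probands),42,31.9
>=1 father's sister (female probands),26,25.0
>=1 maternal first cousin (male probands),296,288.2
>=1 paternal first cousin (male probands),343,305.2
>=1 mother's brother (male probands),21,11.7
>=1 father's brother (male probands),8,8.1
>=1 mother's sister (male probands),25,20.1
>=1 father's sister (male probands),17,15.5
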