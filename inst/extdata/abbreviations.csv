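abbrev,expansion
govt,government
hosp,hospital
inst,institute
med,medical
coll,college
univ,university
dept,department
gen,general
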