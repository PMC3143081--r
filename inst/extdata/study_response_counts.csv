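group,practice,invited,responded
patients_diabetes,pr1,10,4
patients_diabetes,pr2,10,9
patients_diabetes,pr3,10,5
patients_chf,pr1,10,5
patients_chf,pr2,10,7
patients_chf,pr3,7,2
providers,pr1,6,6
providers,pr2,6,6
providers,pr3,10,8
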