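patient_id,has_treatment,has_advice,has_monitoring,hospital_only,comprehensive
z01,FALSE,FALSE,FALSE,FALSE,
z02,FALSE,FALSE,FALSE,FALSE,
z03,FALSE,FALSE,FALSE,FALSE,
e01,TRUE,TRUE,TRUE,TRUE,
e02,TRUE,TRUE,TRUE,TRUE,
e03,FALSE,TRUE,TRUE,TRUE,
e04,FALSE,TRUE,FALSE,TRUE,
r01,TRUE,TRUE,TRUE,FALSE,TRUE
r02,TRUE,TRUE,TRUE,FALSE,TRUE
r03,TRUE,TRUE,TRUE,FALSE,TRUE
r04,TRUE,TRUE,TRUE,FALSE,TRUE
r05,TRUE,TRUE,TRUE,FALSE,TRUE
r06,TRUE,TRUE,TRUE,FALSE,TRUE
r07,TRUE,TRUE,TRUE,FALSE,TRUE
r08,TRUE,TRUE,TRUE,FALSE,TRUE
r09,TRUE,TRUE,TRUE,FALSE,TRUE
r10,TRUE,TRUE,TRUE,FALSE,TRUE
r11,TRUE,TRUE,TRUE,FALSE,FALSE
r12,TRUE,TRUE,TRUE,FALSE,FALSE
r13,TRUE,TRUE,TRUE,FALSE,FALSE
r14,TRUE,TRUE,TRUE,FALSE,FALSE
r15,TRUE,TRUE,TRUE,FALSE,FALSE
r16,TRUE,TRUE,TRUE,FALSE,FALSE
r17,TRUE,FALSE,TRUE,FALSE,FALSE
r18,TRUE,FALSE,TRUE,FALSE,FALSE
r19,TRUE,FALSE,TRUE,FALSE,FALSE
r20,TRUE,FALSE,TRUE,FALSE,FALSE
r21,TRUE,FALSE,TRUE,FALSE,FALSE
r22,TRUE,FALSE,TRUE,FALSE,FALSE
r23,FALSE,FALSE,TRUE,FALSE,FALSE
r24,FALSE,FALSE,TRUE,FALSE,FALSE
r25,FALSE,FALSE,TRUE,FALSE,FALSE
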