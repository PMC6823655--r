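# Default three-tier domain weighting: over-weight (1.20) the
# social/environmental, psychosocial and medical-complexity domains,
# neutral (1.00) attachment, ADLs and risk of harm, under-weight (0.75)
# service density, relationships and hospital utilization.
q1: 1.00
q2: 0.75
q3: 1.20
q4: 1.20
q5: 0.75
q6: 1.00
q7: 1.20
q8: 0.75
q9: 1.00
provenance: default three-tier staff-survey weighting (1.20 / 1.00 / 0.75)
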