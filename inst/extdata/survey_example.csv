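domain,not_important,slightly_important,moderately_important,important,very_important
q1,1,2,5,12,9
q2,3,6,8,8,4
q3,0,1,3,10,15
q4,0,1,3,11,14
q5,4,5,7,9,4
q6,1,3,6,11,8
q7,0,0,4,10,15
q8,4,6,7,8,4
q9,1,2,6,12,8
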