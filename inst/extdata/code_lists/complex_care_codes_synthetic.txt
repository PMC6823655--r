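# Synthetic placeholder list standing in for a complex-care eligibility
# code list (such as the GPSC complex-care diagnostic codes, which are not
# redistributable here). One code per line; '#' starts a comment.
E10
E11
I50
J44
N18
B18.2
B20
G40
I25
K74
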