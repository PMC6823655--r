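# Synthetic placeholder list of substance-use / mental-health (SU/MH)
# diagnosis codes, loosely modelled on ICD-10 chapter F ranges.
# One code per line; '#' starts a comment. Replace with the locally
# maintained SU/MH code list in deployment.
F10
F11
F12
F13
F14
F19
F20
F25
F29
F31
F32
F33
F41
F43
F60
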