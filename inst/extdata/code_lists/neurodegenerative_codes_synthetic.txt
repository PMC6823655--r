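# Synthetic placeholder list of chronic neurodegenerative disorder codes.
# One code per line; '#' starts a comment.
G20
G30
G31
G35
F01
F03
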