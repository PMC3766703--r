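# Interface salt bridges between linker helix 19 and core helix 17
# chain:resnum:resname chain:resnum:resname [cutoff A]
A:710:GLU A:621:ARG 4.0
A:707:ASP A:624:ARG 4.0
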