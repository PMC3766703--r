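# Four-domain decomposition of human topoisomerase IB (765 aa)
# name first last (inclusive, author numbering)
N-terminal 1 214
core 215 635
linker 636 712
C-terminal 713 765
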