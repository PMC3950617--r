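# Maximum wait to first physician assessment, minutes, per CTAS level.
# Level I ("immediate") is represented by a 3-minute bound.
ctas_1: 3
ctas_2: 15
ctas_3: 30
ctas_4: 60
ctas_5: 120
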