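variable	carrier	noncarrier
n	781	5573
alcohol_nondrinker	331	2128
alcohol_lt2	258	1824
alcohol_2to6	109	820
alcohol_ge6	83	792
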