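cluster	significant	not_significant
A1	12	5
A2	1	3
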