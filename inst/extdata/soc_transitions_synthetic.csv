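cycle,from_state,to_state,probability
1,mild,mild,0.85
1,mild,moderate,0.13
1,mild,severe,0.02
1,moderate,mild,0.06
1,moderate,moderate,0.84
1,moderate,severe,0.10
1,severe,mild,0.01
1,severe,moderate,0.11
1,severe,severe,0.88
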