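specimen,TC-E,NS-E,TC-B,NS-B,NC-EB,NS-EB
I1,139,15,149,17,110,10
I2,169,18,153,17,118,23
I3,178,16,193,19,165,5
I4,152,18,165,17,118,16
I5,249,17,174,18,204,15
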