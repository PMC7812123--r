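central
precentral
postcentral
superior frontal
middle frontal
inferior frontal
superior temporal
middle temporal
inferior temporal
sylvian
fronto-marginal
orbital
lateral calcarine
lateral occipital
transverse occipital
lunate
ascending ramus sylvian
horizontal ramus sylvian
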