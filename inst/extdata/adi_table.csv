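group,adi
DDT,0.01
HCB,NA
HCH,NA
aldrin,0.0002
endosulfan,0.006
heptachlor,0.0001
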