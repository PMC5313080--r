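"name","DeltaT"
"pyr",2
"pvb",2.413
"cck",2.786
"sca",2.603
"axo",2.519
"bis",0.577
"olm",2
"ivy",2.641
"ngf",2.436
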