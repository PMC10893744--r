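key,value
stage.I-II,0.20
stage.III,0.30
stage.IV,0.50
survival.I-II,0.416
survival.III,0.144
survival.IV,0.030
remoteness.metropolitan,0.81
remoteness.regional_centres,0.0575
remoteness.large_rural,0.06
remoteness.medium_small_rural_plus,0.0725
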