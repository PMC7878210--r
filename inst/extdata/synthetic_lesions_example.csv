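lesion_id,segment,pa_mmhg,pd_rest_mmhg,pd_hyper_mmhg,height_mm
L001,LAD_dist,100,90,80,-56.8
L002,LAD_mid,95,88,76,-46.1
L003,CX_dist,105,96,85,28.0
L004,RCA_dist,100,93,81,18.0
L005,PL,90,82,72,29.7
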