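segment,syntax_number,syntax_name
LAD_prox,6,Proximal LAD
LAD_mid,7,Mid LAD
LAD_dist,8,Apical (distal) LAD
CX_prox,11,Proximal circumflex
CX_dist,13,Distal circumflex
RCA_prox,1,RCA proximal
RCA_mid,2,RCA mid
RCA_dist,3,RCA distal
PL,16,Posterolateral branch (from RCA in right dominance)
PD,4,Posterior descending artery (from RCA in right dominance)
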