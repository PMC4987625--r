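antigen_id,coating_nM,a0_nM,absorbance
full_antigen,3.5,0,1
full_antigen,3.5,7,0.026426
full_antigen,3.5,15,0.012508
full_antigen,3.5,30,0.006293
full_antigen,3.5,60,0.003157
full_antigen,3.5,120,0.001581
full_antigen,3.5,240,0.000791
full_antigen,3.5,480,0.000396
full_antigen,7,0,1
full_antigen,7,7,0.026426
full_antigen,7,15,0.012508
full_antigen,7,30,0.006293
full_antigen,7,60,0.003157
full_antigen,7,120,0.001581
full_antigen,7,240,0.000791
full_antigen,7,480,0.000396
full_antigen,14,0,1
full_antigen,14,7,0.026426
full_antigen,14,15,0.012508
full_antigen,14,30,0.006293
full_antigen,14,60,0.003157
full_antigen,14,120,0.001581
full_antigen,14,240,0.000791
full_antigen,14,480,0.000396
full_antigen,28,0,1
full_antigen,28,7,0.026426
full_antigen,28,15,0.012508
full_antigen,28,30,0.006293
full_antigen,28,60,0.003157
full_antigen,28,120,0.001581
full_antigen,28,240,0.000791
full_antigen,28,480,0.000396
fragment_C,3.5,0,1
fragment_C,3.5,7,0.376114
fragment_C,3.5,15,0.219563
fragment_C,3.5,30,0.12332
fragment_C,3.5,60,0.065712
fragment_C,3.5,120,0.033972
fragment_C,3.5,240,0.01728
fragment_C,3.5,480,0.008715
fragment_C,7,0,1
fragment_C,7,7,0.376114
fragment_C,7,15,0.219563
fragment_C,7,30,0.12332
fragment_C,7,60,0.065712
fragment_C,7,120,0.033972
fragment_C,7,240,0.01728
fragment_C,7,480,0.008715
fragment_C,14,0,1
fragment_C,14,7,0.376114
fragment_C,14,15,0.219563
fragment_C,14,30,0.12332
fragment_C,14,60,0.065712
fragment_C,14,120,0.033972
fragment_C,14,240,0.01728
fragment_C,14,480,0.008715
fragment_C,28,0,1
fragment_C,28,7,0.376114
fragment_C,28,15,0.219563
fragment_C,28,30,0.12332
fragment_C,28,60,0.065712
fragment_C,28,120,0.033972
fragment_C,28,240,0.01728
fragment_C,28,480,0.008715
truncated_fragment,3.5,0,1
truncated_fragment,3.5,7,1
truncated_fragment,3.5,15,1
truncated_fragment,3.5,30,1
truncated_fragment,3.5,60,1
truncated_fragment,3.5,120,1
truncated_fragment,3.5,240,1
truncated_fragment,3.5,480,1
truncated_fragment,7,0,1
truncated_fragment,7,7,1
truncated_fragment,7,15,1
truncated_fragment,7,30,1
truncated_fragment,7,60,1
truncated_fragment,7,120,1
truncated_fragment,7,240,1
truncated_fragment,7,480,1
truncated_fragment,14,0,1
truncated_fragment,14,7,1
truncated_fragment,14,15,1
truncated_fragment,14,30,1
truncated_fragment,14,60,1
truncated_fragment,14,120,1
truncated_fragment,14,240,1
truncated_fragment,14,480,1
truncated_fragment,28,0,1
truncated_fragment,28,7,1
truncated_fragment,28,15,1
truncated_fragment,28,30,1
truncated_fragment,28,60,1
truncated_fragment,28,120,1
truncated_fragment,28,240,1
truncated_fragment,28,480,1
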