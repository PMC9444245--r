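population,marker,layer_group,animal,n_tracer,n_marker_pos
nac,calb1,L2/3,A01,128,84
nac,calb1,L2/3,A02,101,71
nac,calb1,L2/3,A03,60,42
nac,calb1,L5a-5b-6,A01,287,7
nac,calb1,L5a-5b-6,A02,200,4
nac,calb1,L5a-5b-6,A03,168,7
nac,ctip2,L2/3-5a,A01,62,9
nac,ctip2,L2/3-5a,A02,356,9
nac,ctip2,L2/3-5a,A03,349,27
nac,ctip2,L5b-6,A01,37,22
nac,ctip2,L5b-6,A02,29,20
nac,ctip2,L5b-6,A03,138,88
nac,foxp2,L2/3-5a-5b,A01,288,5
nac,foxp2,L2/3-5a-5b,A02,357,10
nac,foxp2,L2/3-5a-5b,A03,173,0
nac,foxp2,L6,A01,20,4
nac,foxp2,L6,A02,24,3
nac,foxp2,L6,A03,0,0
vta,calb1,L2/3,A01,4,4
vta,calb1,L2/3,A02,2,2
vta,calb1,L2/3,A03,5,2
vta,calb1,L5a-5b-6,A01,371,3
vta,calb1,L5a-5b-6,A02,452,2
vta,calb1,L5a-5b-6,A03,331,2
vta,ctip2,L2/3-5a,A01,1,1
vta,ctip2,L2/3-5a,A02,2,0
vta,ctip2,L2/3-5a,A03,1,0
vta,ctip2,L5b-6,A01,152,144
vta,ctip2,L5b-6,A02,163,158
vta,ctip2,L5b-6,A03,187,178
vta,foxp2,L2/3-5a-5b,A01,162,17
vta,foxp2,L2/3-5a-5b,A02,347,22
vta,foxp2,L2/3-5a-5b,A03,411,38
vta,foxp2,L6,A01,393,347
vta,foxp2,L6,A02,283,219
vta,foxp2,L6,A03,275,195
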