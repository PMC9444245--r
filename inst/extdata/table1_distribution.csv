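population,axis,stratum,animal,count
nac,ap_bin,>2.80 mm,pooled,7
nac,ap_bin,2.80-2.35 mm,pooled,271
nac,ap_bin,2.34-1.99 mm,pooled,513
nac,ap_bin,1.98-1.71 mm,pooled,238
nac,ap_bin,1.70-1.42 mm,pooled,13
nac,ap_bin,<1.42 mm,pooled,0
vta,ap_bin,>2.80 mm,pooled,23
vta,ap_bin,2.80-2.35 mm,pooled,221
vta,ap_bin,2.34-1.99 mm,pooled,530
vta,ap_bin,1.98-1.71 mm,pooled,864
vta,ap_bin,1.70-1.42 mm,pooled,115
vta,ap_bin,<1.42 mm,pooled,125
nac,subregion,Cg2,A01,0
nac,subregion,Cg2,A02,0
nac,subregion,Cg2,A03,0
nac,subregion,Cg1,A01,2
nac,subregion,Cg1,A02,26
nac,subregion,Cg1,A03,4
nac,subregion,PrL,A01,49
nac,subregion,PrL,A02,194
nac,subregion,PrL,A03,54
nac,subregion,IL,A01,10
nac,subregion,IL,A02,35
nac,subregion,IL,A03,14
nac,subregion,MO,A01,135
nac,subregion,MO,A02,404
nac,subregion,MO,A03,82
nac,subregion,DP,A01,2
nac,subregion,DP,A02,16
nac,subregion,DP,A03,0
nac,subregion,DTT,A01,0
nac,subregion,DTT,A02,15
nac,subregion,DTT,A03,0
vta,subregion,Cg2,A01,26
vta,subregion,Cg2,A02,16
vta,subregion,Cg2,A03,22
vta,subregion,Cg1,A01,53
vta,subregion,Cg1,A02,42
vta,subregion,Cg1,A03,73
vta,subregion,PrL,A01,95
vta,subregion,PrL,A02,257
vta,subregion,PrL,A03,153
vta,subregion,IL,A01,20
vta,subregion,IL,A02,67
vta,subregion,IL,A03,88
vta,subregion,MO,A01,71
vta,subregion,MO,A02,128
vta,subregion,MO,A03,199
vta,subregion,DP,A01,68
vta,subregion,DP,A02,111
vta,subregion,DP,A03,130
vta,subregion,DTT,A01,64
vta,subregion,DTT,A02,86
vta,subregion,DTT,A03,109
nac,layer,L1,A01,1
nac,layer,L1,A02,4
nac,layer,L1,A03,1
nac,layer,L2/3,A01,71
nac,layer,L2/3,A02,221
nac,layer,L2/3,A03,32
nac,layer,L5a,A01,92
nac,layer,L5a,A02,360
nac,layer,L5a,A03,119
nac,layer,L5b,A01,25
nac,layer,L5b,A02,83
nac,layer,L5b,A03,1
nac,layer,L6,A01,9
nac,layer,L6,A02,22
nac,layer,L6,A03,1
vta,layer,L1,A01,1
vta,layer,L1,A02,0
vta,layer,L1,A03,0
vta,layer,L2/3,A01,30
vta,layer,L2/3,A02,9
vta,layer,L2/3,A03,9
vta,layer,L5a,A01,10
vta,layer,L5a,A02,7
vta,layer,L5a,A03,5
vta,layer,L5b,A01,194
vta,layer,L5b,A02,434
vta,layer,L5b,A03,466
vta,layer,L6,A01,162
vta,layer,L6,A02,257
vta,layer,L6,A03,294
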