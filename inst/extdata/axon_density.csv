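group,animal,length_nac_mm,length_vta_mm,volume_nac_mm3,volume_vta_mm3,density_nac_mm_per_mm3,density_vta_mm_per_mm3,relative_density
NAc,A01,907.58,30.80,0.0068,0.018,49215.43,4539.63,0.092
NAc,A02,1385.42,24.23,0.0060,0.020,69073.73,4042.84,0.059
NAc,A03,401.99,9.70,0.0028,0.019,20991.09,3519.42,0.17
VTA,A01,130.72,196.69,0.0067,0.017,7578.49,29542.50,3.90
VTA,A02,129.94,161.77,0.0061,0.016,7954.40,26648.57,3.35
VTA,A03,46.42,63.91,0.0064,0.014,3206.06,9953.67,3.10
Rbp4,A01,597.27,299.93,0.0069,0.019,31674.39,43542.44,1.37
Rbp4,A02,617.26,353.48,0.0059,0.0089,69696.59,60044.90,0.86
Rbp4,A03,1323.86,99.42,0.0032,0.016,80501.53,31307.55,0.39
Thy1,A01,1708.58,517.52,0.0058,0.016,104685.07,88715.34,0.85
Thy1,A02,2719.73,459.37,0.0068,0.016,166781.92,67511.08,0.40
Thy1,A03,2807.45,398.95,0.0057,0.013,210241.59,69900.41,0.33
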