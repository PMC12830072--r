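chromophore,wavelength_nm,mu_a_mm_inv,mu_s_mm_inv
HbO2,532,23.499,NA
HbO2,545,25.784,NA
HbO2,558,16.913,NA
HbO2,571,24.718,NA
Hb,532,21.736,NA
Hb,545,25.6,NA
Hb,558,28.404,NA
Hb,571,19.722,NA
collagen,532,0.025647,0.13834
collagen,545,0.0202452,0.14249
collagen,558,0.0160705,0.14414
collagen,571,0.0128246,0.14509
melanin,532,0.124678,0.022589
melanin,545,0.1127474,0.022654
melanin,558,0.1022006,0.021333
melanin,571,0.0928501,0.019359
lipid,532,3.206611911e-06,NA
lipid,545,4.53087659e-06,NA
lipid,558,6.445095905e-06,NA
lipid,571,8.981495858e-06,NA
water,532,1e-04,NA
water,545,0.0001266927391,NA
water,558,0.0001596177384,NA
water,571,0.0002000321783,NA
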