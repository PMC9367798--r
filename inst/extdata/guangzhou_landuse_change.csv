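class,area_2020,area_2030_nd,area_2030_ep
farmland,1998.29,1728.03,1738.54
woodland,3019.18,2792.02,3129.06
grassland,103.79,130.41,151.21
water,580.71,596.76,598.48
construction,1541.73,1996.31,1627.21
unused,2.08,2.25,1.28
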