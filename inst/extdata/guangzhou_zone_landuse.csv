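class,scenario,UDZ,EOZ,EBZ,ECZ
farmland,ND,50.29,476.94,1026.80,174.00
farmland,EP,42.26,511.03,1057.31,127.94
woodland,ND,4.73,66.84,516.94,2203.51
woodland,EP,2.21,213.55,611.46,2301.84
grassland,ND,2.68,27.87,61.07,38.79
grassland,EP,2.35,17.64,75.98,55.24
water,ND,31.44,107.44,264.66,193.22
water,EP,32.34,115.68,240.52,209.94
construction,ND,952.37,549.60,384.95,109.39
construction,EP,962.35,370.79,270.17,23.90
unused,ND,0.00,0.19,1.98,0.08
unused,EP,0.00,0.19,0.96,0.13
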