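zone,area_km2
ECZ,2718.99
EBZ,2256.40
EOZ,1228.88
UDZ,1041.51
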