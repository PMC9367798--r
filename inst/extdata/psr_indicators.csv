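indicator,description,criteria,factor,attribute,weight
D1,Per farmland chemical fertilizer (kg/ha),pressure,environmental_pollution,negative,0.005
D2,Per farmland pesticide (kg/ha),pressure,environmental_pollution,negative,0.012
D3,Population density (P/km2),pressure,population_growth,negative,0.034
D4,Population growth rate (permille),pressure,population_growth,negative,0.029
D5,Proportion of construction (%),pressure,urban_expansion,negative,0.074
D6,Urbanization rate (%),pressure,urban_expansion,negative,0.021
D7,Proportion of woodland (%),state,environmental_quality,positive,0.082
D8,Proportion of water area (%),state,environmental_quality,positive,0.138
D9,Economic density (yuan/km2),state,economic_condition,negative,0.091
D10,Per capita GDP (yuan/P),state,economic_condition,negative,0.041
D11,Per capita farmland (ha/P),state,resource_reserves,positive,0.045
D12,Per capita public green space (ha/P),state,resource_reserves,positive,0.024
D13,Per capita land reserve resources (ha/P),state,resource_reserves,positive,0.074
D14,Attainment rate of industrial waste water discharge (%),response,pollution_treatment,positive,0.015
D15,Disposal rate of household garbage (%),response,pollution_treatment,positive,0.009
D16,Proportion of tertiary industry value in GDP (%),response,economic_input,negative,0.072
D17,Proportion of environment protection investment in GDP (%),response,economic_input,positive,0.085
D18,Newly added soil erosion control area (ha),response,engineering_governance,positive,0.043
D19,Afforestation renewal area (ha),response,engineering_governance,positive,0.106
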