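chemical,css_per_unit_dose,exposure,pod_rfd
Mercuric chloride,7.2,2.1e-05,0.02
Cadmium chloride,5.8,1.4e-04,0.005
Potassium chromate (VI),3.1,6.3e-05,0.09
Zinc chloride,1.9,8.5e-04,0.3
Naphthalene,0.8,3.2e-04,0.2
Fluoranthene,1.6,5.5e-05,1.2
"p,p'-DDT",12.4,4.1e-05,0.05
Dieldrin,9.7,1.8e-05,0.005
Heptachlor,8.3,9.6e-06,0.15
Lindane,4.4,2.7e-05,0.33
Chlorpyrifos,2.6,7.9e-05,0.03
Parathion,1.2,1.1e-05,0.07
Pentachlorophenol,6.1,4.8e-05,0.5
"2,4-dinitrotoluene",0.9,2.2e-05,0.2
Dibutyl phthalate,1.4,6.7e-04,0.6
Di(2-ethylhexyl) phthalate,2.2,1.3e-03,0.06
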