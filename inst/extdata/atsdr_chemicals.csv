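chemical,class,cas,atsdr_rank
Lead nitrate,Inorganic substances,10099-74-8,2
Mercuric chloride,Inorganic substances,7487-94-7,3
Cadmium chloride,Inorganic substances,10108-64-2,7
Potassium chromate (VI),Inorganic substances,7789-00-6,17
Cobalt chloride,Inorganic substances,7646-79-9,51
Nickel chloride,Inorganic substances,7718-54-9,57
Zinc chloride,Inorganic substances,7646-85-7,75
Benzo(b)fluoranthene,PAHs,205-99-2,10
Benzo(a)anthracene,PAHs,56-55-3,38
Naphthalene,PAHs,91-20-3,81
Fluoranthene,PAHs,206-44-0,138
Acenaphthene,PAHs,83-32-9,171
"p,p'-DDT",Pesticides,50-29-3,13
Dieldrin,Pesticides,60-57-1,18
Aldrin,Pesticides,309-00-2,25
"p,p'-DDD",Pesticides,72-54-8,26
Heptachlor,Pesticides,76-44-8,28
Lindane,Pesticides,58-89-9,34
Disulfoton,Pesticides,298-04-4,37
Endrin,Pesticides,72-20-8,40
Diazinon,Pesticides,333-41-5,41
Endosulfan,Pesticides,115-29-7,44
Heptachlor epoxide,Pesticides,1024-57-3,47
"o,p'-DDT",Pesticides,789-02-6,53
Methoxychlor,Pesticides,72-43-5,55
Chlorpyrifos,Pesticides,2921-88-2,64
"2,4-dinitrophenol",Pesticides,51-28-5,89
Ethion,Pesticides,563-12-2,99
Azinphos-methyl,Pesticides,86-50-0,131
Dicofol,Pesticides,115-32-2,145
Parathion,Pesticides,56-38-2,148
Trifluralin,Pesticides,1582-09-8,157
Benzidine,Other industrial chemicals,92-87-5,30
Pentachlorophenol,Other industrial chemicals,87-86-5,54
"2,4,6-trichlorophenol",Other industrial chemicals,88-06-2,85
"2,4-dinitrotoluene",Other industrial chemicals,121-14-2,98
"2-Methyl-4,6-dinitrophenol",Other industrial chemicals,534-52-1,100
"1,2,3-Trichlorobenzene",Other industrial chemicals,87-61-6,137
"2,4,5-Trichlorophenol",Other industrial chemicals,95-95-4,142
p-Cresol,Other industrial chemicals,106-44-5,175
Dibutyl phthalate,Phthalates,84-74-2,58
Di(2-ethylhexyl) phthalate,Phthalates,117-81-7,77
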