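index,label,states
1,Lobes,semicircular or involuted;spiral
2,Basal membrane,absent;present
3,Radiolar flanges,absent or reduced to ridges;present
4,Serrations of radiolar flanges,absent;present
5,Transverse pigment bands on radioles,absent;present
6,Stylodes,absent;present
7,Number of rows of vacuolated cells supporting radioles,four;more than four
8,Radiolar eyes,absent;present
9,Radiolar eyes arrangement,ocelli;unpaired proximal compound eyes on radiole dorsal margin;unpaired terminal compound eyes on inner peduncule;paired compound eyes
10,Dorsal basal flanges,absent;present
11,Press-stud structure present on dorsal basal flanges,absent;present
12,Ventral basal flanges,absent;present
13,Dorsal lip radiolar appendage vacuolated cells (skeleton),absent;present
14,Dorsal pinnular appendages,absent;present
15,Position of ventral sacs,inside the radiolar crown;outside the radiolar crown
16,Dorsal margin of posterior peristomial ring collar,widely separated;fused to the faecal groove
17,Interramal eyespots,absent;present
18,Number of thoracic segments,8;generally less than 8;generally more than 8
19,Gap between thoracic tori and ventral shields,absent;gap in anterior thoracic segments;gap in all thoracic segments
20,Thoracic chaetal fascicles (notopodia),transverse rows;longitudinal bundles
21,Inferior thoracic notochaetae shape,paleate;spine-like
22,Rows of teeth on thoracic uncini,few (1-5);numerous (>5)
23,Length of thoracic uncini handles,medium;short
24,Thoracic companion chaetae,absent;present
25,Abdominal neurochaetal tori,transverse ridges;conical lobes
26,Abdominal neurochaetal fascicles,transverse row(s);spiralled
27,Superior row of abdominal neurochaetal fascicles,elongated narrowly hooded;broadly hooded
28,Inferior row of abdominal chaetae,spine-like;broadly hooded
29,Abdominal uncini number of rows,few (1-5);numerous (>5)
30,Abdominal uncini breast,well developed expanded;narrow swelling
31,Length of abdominal uncini handles,short;medium
32,Pygidial shape,rim;bilobed
33,Scissiparity,absent;present
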