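taxon,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33
Pseudopotamilla cf. reniformis,0,0,0,-,0,0,1,1,1,1,0,1,0,1,0,1,0,0,2,0,0,1,0,1,0,0,1,1,1,1,0,1,?
Bispira manicata,0,1,1,0,1,0,1,1,3,0,-,0,1,0,1,0,1,2,2,1,1,1,0,1,1,1,0,0,1,0,0,0,1
Bispira porifera,0,1,0,-,0,0,1,0,-,1,0,0,1,1,1,0,1,0,2,1,1,1,0,1,1,1,0,0,1,0,0,0,?
Bispira serrata,0,1,1,1,0,0,1,1,3,1,0,0,1,1,1,0,1,0,2,1,1,0,0,1,1,1,0,0,0,0,0,1,?
Branchiomma sp. 1,0,0,0,-,1,1,0,1,3,0,-,0,1,1,1,0,1,0,0,1,1,0,1,0,1,1,0,0,0,0,0,1,1
Branchiomma bairdi,0,0,0,-,1,1,0,1,3,0,-,0,1,1,1,0,1,0,0,1,1,0,1,0,1,1,0,0,0,0,0,1,1
Sabella spallanzanii,1,1,0,-,1,0,0,0,-,0,-,0,1,0,1,0,1,0,1,1,1,1,0,1,1,1,0,0,1,0,0,0,1
Sabella pavonina,1,1,0,-,1,0,0,0,-,0,-,0,1,0,1,0,1,0,2,1,1,1,0,1,1,1,0,0,1,0,0,0,1
Sabellastarte australiensis,1,1,0,-,0,0,1,0,-,1,0,0,1,0,0,1,1,0,0,1,1,1,0,0,1,1,0,0,1,0,1,0,1
Sabellastarte sp.,1,1,0,-,0,0,1,0,-,1,0,0,1,0,0,1,1,0,0,1,1,1,0,0,1,1,0,0,1,0,1,0,1
Stylomma palmatum,0,1,1,0,0,0,1,1,2,1,1,0,0,0,0,0,1,0,0,1,1,1,0,1,1,1,0,0,1,0,0,0,?
Stylomma juani,0,1,1,1,0,0,1,1,0,1,1,0,0,0,0,0,1,0,0,1,1,1,0,1,1,1,0,0,1,0,0,0,?
Pseudobranchiomma emersoni,0,0,1,1,?,0,0,0,-,0,-,0,1,0,1,0,1,1,2,1,1,0,1,0,1,1,0,0,0,0,0,1,1
Pseudobranchiomma cf. emersoni (Australia),0,0,1,1,1,0,0,0,-,0,-,0,1,0,1,0,1,1,2,1,1,0,1,0,1,1,0,0,0,0,0,1,?
Pseudobranchiomma minima,0,0,0,-,1,0,0,0,-,0,-,0,1,0,1,0,1,1,1,1,1,0,1,0,1,1,0,0,0,0,0,?,1
Pseudobranchiomma orientalis,0,1,1,1,1,0,?,0,-,0,-,0,1,0,1,0,1,0,2,1,1,0,1,0,1,1,0,0,0,0,0,1,?
Pseudobranchiomma cf. orientalis (Australia),0,1,1,1,1,0,1,0,-,0,-,0,1,0,1,0,1,0,2,1,1,0,1,0,1,1,0,0,0,0,0,1,?
Pseudobranchiomma pallida sp. n.,0,0,1,1,0,0,0,0,-,0,-,0,1,0,1,0,1,1,1,1,1,0,1,0,1,1,0,0,0,0,0,?,?
Pseudobranchiomma paraemersoni,0,0,1,1,1,0,0,0,-,0,-,0,1,0,1,0,1,1,2,1,1,0,1,0,1,1,0,0,0,0,0,?,?
Pseudobranchiomma paulista,0,0,1,1,1,0,0,0,-,0,-,0,1,?,1,0,1,V,2,1,1,0,1,0,1,1,0,0,0,0,0,?,?
Pseudobranchiomma perkinsi,0,0,0,-,0,0,0,1,3,0,-,0,1,0,1,0,1,2,2,1,1,0,1,0,1,1,0,0,0,0,0,1,1
Pseudobranchiomma punctata,0,1,0,-,1,0,1,0,-,1,0,0,1,0,1,1,1,1,0,1,1,0,1,0,1,1,0,0,0,0,0,?,1
Pseudobranchiomma serratibranchis,0,0,1,1,1,0,0,?,?,?,-,0,1,0,1,0,1,0,0,1,1,?,1,0,1,1,0,0,0,0,0,?,?
Pseudobranchiomma schizogenica,0,1,1,1,1,0,?,0,-,0,-,0,1,0,1,0,1,1,2,1,1,0,1,0,1,1,0,0,0,0,0,1,1
Pseudobranchiomma cf. schizogenica (Australia),0,1,1,1,1,0,0,0,-,0,-,0,1,0,1,0,1,1,2,1,1,0,1,0,1,1,0,0,0,0,0,1,1
Pseudobranchiomma tarantoensis,0,0,0,-,1,0,1,0,-,0,-,0,1,0,1,0,1,0,1,1,1,1,1,0,1,1,0,0,0,0,0,1,0
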