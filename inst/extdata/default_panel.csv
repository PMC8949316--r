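class,carbons,double_bonds,hydroxylation,ion_mode
PE,32,0,none,negative
PE,34,0,none,negative
PE,34,1,none,negative
PE,34,2,none,negative
PE,36,0,none,negative
PE,36,1,none,negative
PE,36,2,none,negative
PE,36,4,none,negative
PE,38,1,none,negative
PE,38,4,none,negative
PE,38,5,none,negative
PE,38,6,none,negative
PE,40,4,none,negative
PE,40,6,none,negative
PE_P,34,0,none,negative
PE_P,34,1,none,negative
PE_P,36,1,none,negative
PE_P,36,2,none,negative
PE_P,36,3,none,negative
PE_P,36,4,none,negative
PE_P,38,3,none,negative
PE_P,38,4,none,negative
PE_P,38,5,none,negative
PE_P,38,6,none,negative
PE_P,40,4,none,negative
PE_P,40,5,none,negative
PE_P,40,6,none,negative
PE_P,40,7,none,negative
PI,34,1,none,negative
PI,36,1,none,negative
PI,36,2,none,negative
PI,36,4,none,negative
PI,38,3,none,negative
PI,38,4,none,negative
PI,38,5,none,negative
PI,38,6,none,negative
PI,40,4,none,negative
PI,40,6,none,negative
PS,34,1,none,negative
PS,36,1,none,negative
PS,36,2,none,negative
PS,38,1,none,negative
PS,38,3,none,negative
PS,38,4,none,negative
PS,40,4,none,negative
PS,40,5,none,negative
PS,40,6,none,negative
PS,42,2,none,negative
PG,34,1,none,negative
PG,34,2,none,negative
PG,36,1,none,negative
PG,36,2,none,negative
PG,36,4,none,negative
PG,38,4,none,negative
PG,38,5,none,negative
PG,40,6,none,negative
Sulf,34,1,d,negative
Sulf,36,2,d,negative
Sulf,36,3,d,negative
Sulf,36,4,d,negative
Sulf,38,2,d,negative
Sulf,40,1,d,negative
Sulf,40,2,d,negative
Sulf,42,1,d,negative
Sulf,42,2,d,negative
Sulf,42,3,d,negative
Sulf,44,2,d,negative
Sulf,40,1,t,negative
Sulf,42,1,t,negative
Sulf,42,2,t,negative
PC,30,0,none,positive
PC,32,0,none,positive
PC,32,1,none,positive
PC,32,2,none,positive
PC,34,0,none,positive
PC,34,1,none,positive
PC,34,2,none,positive
PC,36,1,none,positive
PC,36,2,none,positive
PC,36,3,none,positive
PC,36,4,none,positive
PC,38,4,none,positive
PC,38,5,none,positive
PC,38,6,none,positive
PC,40,4,none,positive
PC,40,6,none,positive
SM,34,1,d,positive
SM,34,2,d,positive
SM,36,1,d,positive
SM,36,2,d,positive
SM,38,1,d,positive
SM,38,2,d,positive
SM,40,1,d,positive
SM,40,2,d,positive
SM,42,1,d,positive
SM,42,2,d,positive
SM,42,3,d,positive
SM,44,2,d,positive
HexCer,34,1,d,positive
HexCer,36,1,d,positive
HexCer,38,1,d,positive
HexCer,40,1,d,positive
HexCer,42,1,d,positive
HexCer,42,2,d,positive
HexCer,44,1,d,positive
HexCer,44,2,d,positive
HexCer,40,1,t,positive
HexCer,42,1,t,positive
Cer,34,1,d,positive
Cer,36,1,d,positive
Cer,38,1,d,positive
Cer,40,1,d,positive
Cer,42,1,d,positive
Cer,42,2,d,positive
Cer,44,1,d,positive
Cer,44,2,d,positive
DG,32,0,none,positive
DG,34,0,none,positive
DG,34,1,none,positive
DG,36,1,none,positive
DG,36,2,none,positive
DG,36,4,none,positive
DG,38,4,none,positive
DG,38,6,none,positive
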