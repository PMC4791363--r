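marker
alaS
argS
asnS
aspS
cysS
glnS
gltX
glyS
hisS
ileS
leuS
lysS
metG
pheS
pheT
proS
serS
thrS
trpS
tyrS
valS
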