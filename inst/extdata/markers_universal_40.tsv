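marker
rpsB
rpsC
rpsE
rpsI
rpsJ
rpsK
rpsL
rpsM
rpsS
rplA
rplB
rplC
rplD
rplE
rplF
rplK
rplL
rplM
rplN
rplP
rplS
rplT
rplO
rpoA
rpoB
secY
secE
ffh
ftsY
infC
frr
pgk
pyrG
rpmA
smpB
tsf
nusA
dnaG
rpsG
rpsH
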