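pathway	gene
glycolysis	glk
glycolysis	pgi
glycolysis	pfk
glycolysis	fba
glycolysis	tpi
glycolysis	gapA
glycolysis	pgk
glycolysis	gpmA
glycolysis	eno
glycolysis	pyk
tca_oxidative	gltA
tca_oxidative	acn
tca_oxidative	icd
tca_oxidative	kor
tca_oxidative	suc
tca_oxidative	sdh
tca_oxidative	fumC
tca_oxidative	mdh
cobalamin_synthesis	cysG
cobalamin_synthesis	cobA
cobalamin_synthesis	cobI
cobalamin_synthesis	cobG
cobalamin_synthesis	cobJ
cobalamin_synthesis	cobM
cobalamin_synthesis	cobF
cobalamin_synthesis	cobK
cobalamin_synthesis	cobL
cobalamin_synthesis	cobH
cobalamin_synthesis	cobB
cobalamin_synthesis	cobN
cobalamin_synthesis	cobS
cobalamin_synthesis	cobT
cobalamin_synthesis	cobO
cobalamin_synthesis	cobQ
cobalamin_synthesis	cobC
cobalamin_synthesis	cobD
cobalamin_synthesis	cobP
cobalamin_synthesis	cobU
cobalamin_synthesis	cobV
cobalamin_synthesis	cobW
cobalamin_synthesis	btuR
cobalamin_synthesis	cbiA
cobalamin_synthesis	cbiB
cobalamin_synthesis	cbiC
cobalamin_synthesis	cbiD
cobalamin_synthesis	cbiE
cobalamin_synthesis	cbiT
cobalamin_synthesis	cbiG
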