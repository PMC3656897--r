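id	kind	label	signature_34	signature_10
Leu-ref1	A	Leu	AVCKDIFNHIEPHMLTAACSGHSTLIYKEKGVEG	AKNPLCSYKG
Leu-ref2	A	Leu	AVCKDIFNHIEPHMLTAACSGHSTLIYKEKGVEG	AKNPLCSYKG
Leu-ref3	A	Leu	AVCKDIFNHREPHMLTAACSGHSTLIYKEKGVEG	AKNPLCSYKG
Ser-ref1	A	Ser	AVCGDIFMHIENHMETAAESGHMTVQDKENGVEV	AGMNEEMDNV
Ser-ref2	A	Ser	AVCGDIFMHIENHMETAAESGWMTLIDKENGVEV	AGMNEEMDNV
Ser-ref3	A	Ser	AVCGDIFMHIENHMETAAESGHMTLIDKENGVEV	AGMNEEMDNV
Val-ref1	A	Val	AVCDDIFLHIENHMWTAAGSGHGTLIFKEQGVEK	ADLNWGGFQK
Val-ref2	A	Val	AVCDDIFLHPENHAHTAAWSGHGTLIFKEQGVEK	ADLNHWGFQK
Val-ref3	A	Val	AVCDDIFLHIENHMWTAACSGHGTLIFKEMGVEK	ADLNWCGFMK
C-starter-ref1	C	starter	NA	NA
C-starter-ref2	C	starter	NA	NA
C-starter-ref3	C	starter	NA	NA
C-CE-ref1	C	C/E	NA	NA
C-CE-ref2	C	C/E	NA	NA
C-CE-ref3	C	C/E	NA	NA
C-conventional-ref1	C	conventional	NA	NA
C-conventional-ref2	C	conventional	NA	NA
C-conventional-ref3	C	conventional	NA	NA
TE1-ref1	TE	TE1	NA	NA
TE1-ref2	TE	TE1	NA	NA
TE1-ref3	TE	TE1	NA	NA
TE2-ref1	TE	TE2	NA	NA
TE2-ref2	TE	TE2	NA	NA
TE2-ref3	TE	TE2	NA	NA
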