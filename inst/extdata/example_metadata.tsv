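barcode	patient_id	tissue	subset	cluster
SIMBC0000001-1	patient1	P	CD4	GZMK+ Tem CD4
SIMBC0000002-1	patient1	P	CD4	GZMK+ Tem CD4
SIMBC0000003-1	patient2	P	CD4	Treg
SIMBC0000004-1	patient1	P	CD4	naive CD4
SIMBC0000005-1	patient2	P	CD4	naive CD4
SIMBC0000006-1	patient3	P	CD4	naive CD4
SIMBC0000007-1	patient3	P	CD4	Treg
SIMBC0000008-1	patient2	P	CD4	GZMK+ Tem CD4
SIMBC0000009-1	patient2	P	CD4	GZMK+ Tem CD4
SIMBC0000010-1	patient3	N	CD4	Treg
SIMBC0000011-1	patient2	N	CD4	naive CD4
SIMBC0000012-1	patient1	N	CD4	Treg
SIMBC0000013-1	patient1	N	CD4	Treg
SIMBC0000014-1	patient1	N	CD4	Treg
SIMBC0000015-1	patient2	N	CD4	Treg
SIMBC0000016-1	patient2	N	CD4	Tfh
SIMBC0000017-1	patient2	N	CD4	GZMK+ Tem CD4
SIMBC0000018-1	patient2	N	CD4	GZMK+ Tem CD4
SIMBC0000019-1	patient2	N	CD4	GZMK+ Tem CD4
SIMBC0000020-1	patient2	N	CD4	Tfh
SIMBC0000021-1	patient2	N	CD4	Tfh
SIMBC0000022-1	patient2	N	CD4	GZMK+ Tem CD4
SIMBC0000023-1	patient2	N	CD4	GZMK+ Tem CD4
SIMBC0000024-1	patient3	N	CD4	GZMK+ Tem CD4
SIMBC0000025-1	patient2	N	CD4	Treg
SIMBC0000026-1	patient3	N	CD4	Tfh
SIMBC0000027-1	patient3	N	CD4	Tfh
SIMBC0000028-1	patient3	T	CD4	GZMK+ Tem CD4
SIMBC0000029-1	patient3	T	CD4	naive CD4
SIMBC0000030-1	patient3	T	CD4	naive CD4
SIMBC0000031-1	patient3	T	CD4	naive CD4
SIMBC0000032-1	patient1	T	CD4	GZMK+ Tem CD4
SIMBC0000033-1	patient1	T	CD4	naive CD4
SIMBC0000034-1	patient1	T	CD4	naive CD4
SIMBC0000035-1	patient3	T	CD4	naive CD4
SIMBC0000036-1	patient3	T	CD4	naive CD4
SIMBC0000037-1	patient2	T	CD4	naive CD4
SIMBC0000038-1	patient2	T	CD4	naive CD4
SIMBC0000039-1	patient1	T	CD4	Th17
SIMBC0000040-1	patient1	T	CD4	Tfh
SIMBC0000041-1	patient3	T	CD4	naive CD4
SIMBC0000042-1	patient3	T	CD4	naive CD4
SIMBC0000043-1	patient1	T	CD4	naive CD4
SIMBC0000044-1	patient3	T	CD4	naive CD4
SIMBC0000045-1	patient2	T	CD4	Treg
SIMBC0000046-1	patient2	T	CD4	Treg
SIMBC0000047-1	patient2	T	CD4	naive CD4
SIMBC0000048-1	patient2	T	CD4	Treg
SIMBC0000049-1	patient2	T	CD4	Treg
SIMBC0000050-1	patient2	T	CD4	Treg
SIMBC0000051-1	patient1	P	CD8	naive CD8
SIMBC0000052-1	patient2	P	CD8	GZMK+ early Tem
SIMBC0000053-1	patient2	P	CD8	GZMK+ early Tem
SIMBC0000054-1	patient2	P	CD8	terminal Tex
SIMBC0000055-1	patient3	P	CD8	GZMK+ early Tem
SIMBC0000056-1	patient1	P	CD8	naive CD8
SIMBC0000057-1	patient1	P	CD8	naive CD8
SIMBC0000058-1	patient2	P	CD8	GZMK+ early Tem
SIMBC0000059-1	patient2	P	CD8	Temra
SIMBC0000060-1	patient2	P	CD8	terminal Tex
SIMBC0000061-1	patient2	P	CD8	GZMK+ early Tem
SIMBC0000062-1	patient3	P	CD8	terminal Tex
SIMBC0000063-1	patient3	P	CD8	Temra
SIMBC0000064-1	patient1	P	CD8	Temra
SIMBC0000065-1	patient1	P	CD8	Temra
SIMBC0000066-1	patient2	N	CD8	naive CD8
SIMBC0000067-1	patient2	N	CD8	naive CD8
SIMBC0000068-1	patient2	N	CD8	terminal Tex
SIMBC0000069-1	patient2	N	CD8	terminal Tex
SIMBC0000070-1	patient2	N	CD8	terminal Tex
SIMBC0000071-1	patient2	N	CD8	terminal Tex
SIMBC0000072-1	patient1	N	CD8	Temra
SIMBC0000073-1	patient1	N	CD8	terminal Tex
SIMBC0000074-1	patient1	N	CD8	terminal Tex
SIMBC0000075-1	patient1	N	CD8	terminal Tex
SIMBC0000076-1	patient3	T	CD8	ZNF683+CXCR6+ Trm
SIMBC0000077-1	patient3	T	CD8	ZNF683+CXCR6+ Trm
SIMBC0000078-1	patient3	T	CD8	ZNF683+CXCR6+ Trm
SIMBC0000079-1	patient1	T	CD8	Temra
SIMBC0000080-1	patient1	T	CD8	GZMK+ early Tem
SIMBC0000081-1	patient1	T	CD8	GZMK+ early Tem
SIMBC0000082-1	patient1	T	CD8	GZMK+ early Tem
SIMBC0000083-1	patient3	T	CD8	Temra
SIMBC0000084-1	patient3	T	CD8	Temra
SIMBC0000085-1	patient2	T	CD8	ZNF683+CXCR6+ Trm
SIMBC0000086-1	patient3	T	CD8	terminal Tex
SIMBC0000087-1	patient2	T	CD8	terminal Tex
SIMBC0000088-1	patient1	N	CD8	Temra
SIMBC0000089-1	patient2	N	CD4	naive CD4
SIMBC0000090-1	patient3	T	CD8	naive CD8
SIMBC0000091-1	patient2	P	CD4	naive CD4
SIMBC0000092-1	patient2	P	CD4	naive CD4
SIMBC0000093-1	patient2	P	CD4	naive CD4
SIMBC0000094-1	patient1	T	CD4	naive CD4
SIMBC0000095-1	patient1	T	CD4	naive CD4
SIMBC0000096-1	patient2	T	CD4	Treg
SIMBC0000097-1	patient2	T	CD4	Treg
SIMBC0000098-1	patient1	N	CD8	Temra
SIMBC0000099-1	patient1	N	CD8	Temra
SIMBC0000100-1	patient1	N	CD8	Temra
SIMBC0000101-1	patient3	T	CD8	naive CD8
SIMBC0000102-1	patient3	T	CD8	naive CD8
SIMBC0000103-1	patient3	T	CD8	naive CD8
SIMBC0000104-1	patient2	N	CD4	naive CD4
SIMBC0000105-1	patient1	T	CD4	naive CD4
SIMBC0000106-1	patient3	T	CD8	naive CD8
SIMBC0000107-1	patient2	T	CD4	Th17
SIMBC0000109-1	patient2	P	CD4	GZMK+ Tem CD4
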