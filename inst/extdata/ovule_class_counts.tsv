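direction	stage	class	count
up	I	transgressive	5
up	I	po_4x	27
up	I	ploidy	23
up	II	transgressive	15
up	II	po_4x	10
up	II	ploidy	1
up	III	transgressive	16
up	III	po_4x	44
up	III	ploidy	36
up	IV	transgressive	2
up	IV	po_4x	1
up	IV	ploidy	2
down	I	transgressive	6
down	I	po_4x	7
down	I	ploidy	10
down	II	transgressive	18
down	II	po_4x	37
down	II	ploidy	2
down	III	transgressive	9
down	III	po_4x	11
down	III	ploidy	17
down	IV	transgressive	2
down	IV	po_4x	1
down	IV	ploidy	2
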