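alias	canonical
rrn26.r01	rrn26
rrn18.r01	rrn18
nad4.cds.3	nad4
trnq-uug	trnQ
trnq	trnQ
psba_1	psbA
rps12a	rps12
rps12b	rps12
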