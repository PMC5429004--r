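category	pairs
total	812092660
chloroplast	7712928
mitochondria	8657582
transcriptome	104668765
unaligned	691053385
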