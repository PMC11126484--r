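sample	soil	treatment	fraction_class
AS_HF_1	acidic	15N-urea	HF
AS_HF_2	acidic	15N-urea	HF
AS_CK_1	acidic	CK	light
AS_CK_2	acidic	CK	light
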