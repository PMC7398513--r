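site_name	marker	ref_offset_0based	allowed_bases
mCOI1164D	COIB	240	A,G,T
mCOI1287R	COIB	363	A,G
gTpi183Y	TPI	182	C,T
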