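synonym	canonical
TEMOZOLOMIDE	TEMOZOLOMIDE
TEMODAR	TEMOZOLOMIDE
TEMODAL	TEMOZOLOMIDE
TEMCAD	TEMOZOLOMIDE
TEMOMEDAC	TEMOZOLOMIDE
TEMOZOLOMIDA	TEMOZOLOMIDE
TEMOZOLOMIDUM	TEMOZOLOMIDE
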