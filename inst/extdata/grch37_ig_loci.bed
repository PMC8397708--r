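14	106032613	107288051	IGH
2	89156873	90274235	IGK
22	22380473	23265085	IGL
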