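# PROSITE pattern PS00014 (ER_TARGET): C-terminal endoplasmic-reticulum
# retention signal, KDEL-type. One pattern per non-comment line:
# <pattern_id><TAB><pattern>
PS00014	[KRHQSA]-[DENQ]-E-L>
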