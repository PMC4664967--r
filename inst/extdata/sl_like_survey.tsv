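sl_variant	hits	copepod_hits
CopepodSL	1220	1156
CopepodSL-like1a	157	NA
CopepodSL-like1b	71	NA
CopepodSL-like2a	45	28
CopepodSL-like2b	28	16
CopepodSL-like2c	15	3
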