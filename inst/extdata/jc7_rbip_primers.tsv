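name	sequence
FLKL	CAAAGCACACGAGGATTCAG
FLKR	CAGGTCCAAATCTCCTCGTG
LTRL	GAAAATTAAATCCAACATGT
LTRR	GAGATTAATTCTTAACAGAA
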