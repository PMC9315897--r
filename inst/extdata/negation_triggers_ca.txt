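# Catalan negation trigger words (normalized forms).
no
sense
nega
descarta
absencia
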