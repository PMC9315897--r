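# Catalan-discriminative function and clinical words (normalized forms).
# Words shared with Spanish spelling are deliberately excluded.
els
les
dels
i
amb
per
aquest
aquesta
sense
fa
des
fins
molt
despres
avui
pacient
refereix
nega
simptomes
simptomatologia
tristesa
tractament
seguiment
millora
anys
mesos
ansietat
depressio
proves
consultes
propera
actualment
ultims
acudeix
acompanyada
intervencio
diagnostic
exploracio
evolucio
bona
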