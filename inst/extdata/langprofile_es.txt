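# Spanish-discriminative function and clinical words (normalized forms).
# Words shared with Catalan spelling are deliberately excluded.
los
las
del
y
con
por
para
una
uno
este
esta
sin
hace
desde
hasta
muy
bien
tras
hoy
paciente
refiere
niega
sintomas
sintomatologia
tristeza
tratamiento
seguimiento
mejoria
anos
meses
ansiedad
depresion
pruebas
consultas
proxima
actualidad
ultimos
acude
acompanada
intervencion
diagnostico
exploracion
evolucion
buena
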