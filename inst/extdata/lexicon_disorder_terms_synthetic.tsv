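surface	language	category	concept_id	canonical
# Synthetic stand-in for the depressive-disorder term dictionary: a
# representative bilingual subset of surface forms for concepts under the
# SNOMED CT "trastorno depresivo" (35489007) hierarchy, not the full
# terminology. Replace via load_lexicon() for real analyses.
trastorno depresivo	es	disorder_term	35489007	trastorno depresivo
trastorn depressiu	ca	disorder_term	35489007	trastorno depresivo
depresión	es	disorder_term	35489007	trastorno depresivo
depressió	ca	disorder_term	35489007	trastorno depresivo
síndrome depresivo	es	disorder_term	35489007	trastorno depresivo
síndrome depressiva	ca	disorder_term	35489007	trastorno depresivo
clínica depresiva	es	disorder_term	35489007	trastorno depresivo
clínica depressiva	ca	disorder_term	35489007	trastorno depresivo
depresión mayor	es	disorder_term	370143000	depresión mayor
depressió major	ca	disorder_term	370143000	depresión mayor
trastorno depresivo mayor	es	disorder_term	370143000	depresión mayor
episodio depresivo	es	disorder_term	871840004	episodio depresivo
episodi depressiu	ca	disorder_term	871840004	episodio depresivo
distimia	both	disorder_term	78667006	distimia
depresión recurrente	es	disorder_term	191659001	depresión recurrente
depressió recurrent	ca	disorder_term	191659001	depresión recurrente
depresión posparto	es	disorder_term	58703003	depresión posparto
depressió postpart	ca	disorder_term	58703003	depresión posparto
ánimo deprimido	es	disorder_term	366979004	ánimo deprimido
ànim deprimit	ca	disorder_term	366979004	ánimo deprimido
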