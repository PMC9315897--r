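# Default depressive-disorder ICD-9-CM code set (configurable stand-in).
# Three-digit entries are hierarchical prefixes covering all subcodes.
296.2
296.3
298.0
300.4
309.0
309.1
311
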