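# hash_algorithm: sha256
# curie_map:
#   tbto: https://example.org/tbto/
#   tccle: https://example.org/tccle/
#   tcell: https://example.org/tcell/
#   tclo: https://example.org/tclo/
#   tdep: https://example.org/tdep/
#   tefo: https://example.org/tefo/
subject_id	predicate_id	object_id	mapping_justification	confidence	author_id	mapping_set_name	mapping_set_version	mapping_set_license	mapping_set_confidence	reasoning_operation	reasoning_factor	supporting_mapping_hashes
tccle:1321N1	skos:exactMatch	tcell:0110	semapv:ManualMappingCuration			toy-secondary	1		0.8			
tccle:1321N1	skos:exactMatch	tefo:0005236	semapv:ManualMappingCuration			toy-secondary	1		0.8			
tcell:0110	oboinowl:hasDbXref	tclo:0001072	semapv:UnspecifiedMatching			toy-primary	1		0.9			
tdep:ACH-000095	skos:exactMatch	tccle:1321N1	semapv:UnspecifiedMatching			toy-primary	1		0.9			
tdep:ACH-000095	skos:exactMatch	tcell:0110	semapv:UnspecifiedMatching			toy-primary	1		0.9			
tefo:0005236	skos:exactMatch	tbto:0000058	semapv:UnspecifiedMatching			toy-primary	1		0.9			
tefo:0005236	skos:exactMatch	tcell:0110	semapv:UnspecifiedMatching			toy-primary	1		0.9			
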