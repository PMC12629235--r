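schema_version: 1
inputs:
- path: toy.sssom.tsv
  kind: sssom
mutations:
- source: oboinowl:hasDbXref
  target: skos:exactMatch
  factor: 0.7
inversions: yes
chains:
  max_path_length: 5
  factor: 1.0
filters:
- kind: cardinality
  action: flag
priority:
- tcell
- tefo
- tdep
- tccle
- tclo
- tbto
outputs:
- kind: sssom
  path: processed.sssom.tsv
- kind: prioritization
  path: prioritization.tsv
- kind: projection
  source: tbto
  target: tclo
  path: projection_tbto_tclo.tsv
- kind: pgraph
  path: pgraph
seed: 1
strict: no
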