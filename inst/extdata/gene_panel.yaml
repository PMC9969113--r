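# Characteristic alteration panel per EOC histological subtype, as curated in
# the literature. Editable: map_clusters / concordance operations accept any
# subtype -> gene-set mapping of this shape.
HGSOC:
  - TP53
  - BRCA1
  - BRCA2
CCOC:
  - ARID1A
  - PIK3CA
  - KRAS
  - PTEN
  - SMARCA4
ENOC:
  - ARID1A
  - PIK3CA
  - KRAS
  - PTEN
  - CTNNB1
MOC:
  - KRAS
  - NRAS
  - ARID1A
  - PIK3CA
  - ERBB2
  - CDKN2A
LGSOC:
  - BRAF
  - KRAS
  - NRAS
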