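min_freq: 0.005
haplotypes:
  '*008':
    rs9266825: C
    rs1882: A
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*004':
    rs9266825: C
    rs1882: G
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*009':
    rs9266825: C
    rs1882: G
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*049':
    rs9266825: C
    rs1882: G
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*010':
    rs9266825: C
    rs1882: G
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*019':
    rs9266825: C
    rs1882: G
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*027':
    rs9266825: C
    rs1882: G
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: A
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
  '*002':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: A
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*007':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: A
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*015':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: A
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*017':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: A
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*068':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: A
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*001':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*012':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*018':
    rs9266825: A
    rs1882: G
    rs9266826: A
    rs9266827: G
    rs9266828: C
    rs9266829: G
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: G
    rs9266831: A
  '*011':
    rs9266825: C
    rs1882: A
    rs9266826: G
    rs9266827: A
    rs9266828: G
    rs9266829: G
    rs140390705: C
    rs1880: C
    rs113015830: T
    rs1131904: A
    rs9266831: G
length_classes:
  '*008': long
  '*004': short
  '*009': short
  '*049': short
  '*010': short
  '*019': short
  '*027': short
  '*002': short
  '*007': short
  '*015': medium
  '*017': medium
  '*068': medium
  '*001': short
  '*012': short
  '*018': short
  '*011': short
subtype_overrides:
  '*004': b
  '*009': b
  '*049': b
  '*010': c
  '*019': c
  '*027': c
  '*002': a
  '*007': b
group_names:
  '*008': UTR1
  '*002': UTR2
  '*001': UTR4
  '*011': UTR7
lineages:
  '*008': LII
  '*004': LII
  '*009': LII
  '*049': LII
  '*010': LII
  '*019': LII
  '*027': LII
  '*002': LI
  '*007': LI
  '*015': LI
  '*017': LI
  '*068': LI
  '*001': LI
  '*012': LI
  '*018': LI
  '*011': LI
indels:
  long:
    position: 952
    kind: insertion
    ref: ''
    alt: G
  medium:
    position: 892
    kind: deletion
    ref: G
    alt: ''
  short:
    position: []
    kind: []
    ref: []
    alt: []
lineage_edits:
  LII:
    position:
    - 120
    - 186
    - 252
    - 318
    - 384
    - 450
    - 516
    - 582
    - 648
    - 714
    - 780
    - 846
    kind:
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    - substitution
    ref:
    - A
    - A
    - A
    - A
    - A
    - A
    - A
    - A
    - A
    - A
    - A
    - A
    alt:
    - C
    - C
    - C
    - C
    - C
    - C
    - C
    - C
    - C
    - C
    - C
    - C
  LI:
    position: []
    kind: []
    ref: []
    alt: []
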