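# Example sample-series configuration (synthetic stage labels).
# Each entry maps a series name to the group labels it includes, mirroring
# the common design of staged developmental studies: overlapping windows of
# whole-embryo stages plus brain-tissue series for later development.
A:
  include: [NF0, NF1, NF10, NF21, NF37, NF41, NF50]
  description: whole embryo including unfertilised egg (NF0-NF50)
B:
  include: [NF1, NF10, NF21, NF37, NF41, NF50]
  description: whole embryo excluding unfertilised egg (NF1-NF50)
C:
  include: [NF0, NF1, NF10, NF21, NF37, NF41]
  description: prior to thyroid gland formation, with egg (NF0-NF41)
D:
  include: [NF1, NF10, NF21, NF37, NF41]
  description: prior to thyroid gland formation (NF1-NF41)
E:
  include: [NF1, NF10]
  description: one cell to mid blastula (NF1-NF10)
F:
  include: [NF21, NF37]
  description: after gastrulation, before thyroid gland formation
G:
  include: [NF21, NF37, NF41]
  description: after gastrulation and thyroid gland formation (NF21-NF41)
H:
  include: [NF37, NF41, NF50]
  description: during thyroid gland formation (NF37-NF50)
AA:
  include: [BR41, BR50, BR58, BR66]
  description: brain from early development through metamorphosis and juvenile
AB:
  include: [BR50, BR58, BR66]
  description: brain from metamorphosis and juvenile stages
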