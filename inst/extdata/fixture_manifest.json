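{
  "settings": {
    "n_cells": 20,
    "lateral_cells": 1,
    "ve_cells": 6,
    "dm_cells": 10
  },
  "seeds": {
    "cream_ivrt": 101,
    "ointment_ivrt": 102,
    "cream_ivpt": 103,
    "ointment_ivpt": 104
  },
  "noise": {
    "replicate_cv": 0.15,
    "n_replicates": [6, 5]
  },
  "synthetic": true
}
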