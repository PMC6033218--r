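{
  "provenance": "Point assignments follow the published Mayo SSIGN (stage, size, grade, necrosis) table as used in the Zigeuner external validation; review against the cited reference before clinical use. Risk bins are configurable; defaults group scores 0-2 / 3-5 / >=6.",
  "T": {"1": 0, "2": 1, "3": 2, "4": 2},
  "N": {"0": 0, "1": 2, "2": 2},
  "M": {"0": 0, "1": 4},
  "G": {"1": 0, "2": 0, "3": 1, "4": 3},
  "necrosis": {"absent": 0, "present": 1},
  "size": {"threshold_cm": 5, "below": 0, "at_or_above": 2},
  "bins": {"low": [0, 2], "intermediate": [3, 5], "high": [6, 99]}
}
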