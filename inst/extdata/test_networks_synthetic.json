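{
  "description": "Synthetic 23-network test battery over three slider variables. The individual structures are constructed (not transcribed from any experimental stimulus set) to satisfy the battery's aggregate design properties: 23 networks; 54 non-zero directed links out of 138 ordered-pair slots (density 0.39); every network carries between 1 and 4 links with all four counts represented; regular and inverse links near-balanced (29 vs 25); and the battery spans single causes, chains, common causes, common effects, feedback loops and cycles. The two single-cause networks double as practice items.",
  "variables": ["X", "Y", "Z"],
  "magnitude": 1,
  "practice": ["single_regular", "single_inverse"],
  "networks": [
    {"name": "single_regular",    "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 0,  "Y->Z": 0,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "single_inverse",    "edges": {"X->Y": -1, "X->Z": 0,  "Y->X": 0,  "Y->Z": 0,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "single_regular_b",  "edges": {"X->Y": 0,  "X->Z": 0,  "Y->X": 0,  "Y->Z": 1,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "single_inverse_b",  "edges": {"X->Y": 0,  "X->Z": 0,  "Y->X": 0,  "Y->Z": 0,  "Z->X": -1, "Z->Y": 0}},
    {"name": "chain_rr",          "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 0,  "Y->Z": 1,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "chain_ii",          "edges": {"X->Y": -1, "X->Z": 0,  "Y->X": 0,  "Y->Z": -1, "Z->X": 0,  "Z->Y": 0}},
    {"name": "chain_ri",          "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 0,  "Y->Z": -1, "Z->X": 0,  "Z->Y": 0}},
    {"name": "common_cause_rr",   "edges": {"X->Y": 1,  "X->Z": 1,  "Y->X": 0,  "Y->Z": 0,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "common_cause_ir",   "edges": {"X->Y": -1, "X->Z": 1,  "Y->X": 0,  "Y->Z": 0,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "common_cause_ii",   "edges": {"X->Y": 0,  "X->Z": 0,  "Y->X": -1, "Y->Z": -1, "Z->X": 0,  "Z->Y": 0}},
    {"name": "common_effect_rr",  "edges": {"X->Y": 0,  "X->Z": 1,  "Y->X": 0,  "Y->Z": 1,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "common_effect_ii",  "edges": {"X->Y": 0,  "X->Z": -1, "Y->X": 0,  "Y->Z": -1, "Z->X": 0,  "Z->Y": 0}},
    {"name": "feedback_rr",       "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 1,  "Y->Z": 0,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "chain_skip_rrr",    "edges": {"X->Y": 1,  "X->Z": 1,  "Y->X": 0,  "Y->Z": 1,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "chain_skip_iir",    "edges": {"X->Y": -1, "X->Z": 1,  "Y->X": 0,  "Y->Z": -1, "Z->X": 0,  "Z->Y": 0}},
    {"name": "cycle_rrr",         "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 0,  "Y->Z": 1,  "Z->X": 1,  "Z->Y": 0}},
    {"name": "cycle_rii",         "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 0,  "Y->Z": -1, "Z->X": -1, "Z->Y": 0}},
    {"name": "feedback_out_rir",  "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": -1, "Y->Z": 1,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "feedback_out_iii",  "edges": {"X->Y": -1, "X->Z": -1, "Y->X": -1, "Y->Z": 0,  "Z->X": 0,  "Z->Y": 0}},
    {"name": "cause_chain_rii",   "edges": {"X->Y": 1,  "X->Z": -1, "Y->X": 0,  "Y->Z": -1, "Z->X": 0,  "Z->Y": 0}},
    {"name": "effect_link_rir",   "edges": {"X->Y": 0,  "X->Z": 0,  "Y->X": 1,  "Y->Z": 1,  "Z->X": -1, "Z->Y": 0}},
    {"name": "double_feedback",   "edges": {"X->Y": 1,  "X->Z": 0,  "Y->X": 1,  "Y->Z": -1, "Z->X": 0,  "Z->Y": -1}},
    {"name": "cycle_extra",       "edges": {"X->Y": -1, "X->Z": -1, "Y->X": 0,  "Y->Z": 1,  "Z->X": 1,  "Z->Y": 0}}
  ]
}
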