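{
  "description": "Published screening-value table rows that do not reproduce under the derivation convention (sRfD = LTD/total rounded to 2 significant figures, half away from zero; WSV computed from the rounded sRfD and rounded to 1 significant figure). The published numbers are kept as ground truth; the recomputed values are recorded here.",
  "table3": [
    {
      "api_name": "Doxepin",
      "field": "srfd_mg_kg_d",
      "printed": 0.00032,
      "computed": 0.00031,
      "note": "0.94/3000 = 0.0003133, which rounds to 0.00031 at 2 significant figures; the printed WSV of 0.9 is consistent with either sRfD."
    },
    {
      "api_name": "Norfloxacin",
      "field": "wsv_ug_L",
      "printed": 10,
      "computed": 9,
      "note": "0.0033 x 0.8 x 1000 / 0.289 = 9.13, which rounds to 9 at 1 significant figure; the printed sRfD reproduces exactly."
    }
  ],
  "table4": [
    {
      "api_name": "Acetaminophen (one tablet/day)",
      "field": "wsv_ug_L",
      "printed": 9,
      "computed": 0.9,
      "note": "LTD 3.75 over total 3000 with RSC 0.2 gives 0.9 ug/L as printed inputs stand; flagged inconsistent_as_printed."
    },
    {
      "api_name": "Acetaminophen (six tablets/day)",
      "field": "wsv_ug_L",
      "printed": 50,
      "computed": 5,
      "note": "LTD 22.5 over total 3000 with RSC 0.2 gives 5 ug/L as printed inputs stand; flagged inconsistent_as_printed."
    },
    {
      "api_name": "17a-Ethinylestradiol",
      "field": "wsv_ug_L",
      "printed": 0.0001,
      "computed": 0.0004,
      "note": "LTD 0.00044 over total 3000 with RSC 0.8 gives 0.0004 ug/L; flagged inconsistent_as_printed."
    },
    {
      "api_name": "Venlafaxine",
      "field": "wsv_ug_L",
      "printed": 0.3,
      "computed": 20,
      "note": "The stated LTD of 25 mg/kg-d is inconsistent with the printed WSV of 0.3 ug/L under the stated factors; flagged inconsistent_as_printed."
    }
  ]
}
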