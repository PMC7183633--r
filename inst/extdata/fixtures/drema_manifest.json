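{
  "study_id": "drema",
  "n_modules": 1,
  "modules": [
    {
      "id": "week1_unwind",
      "name": "Week 1: Unwind",
      "n_sections": 1,
      "element_type_counts": {
        "media": 2,
        "instruction": 1,
        "checkbox": 1,
        "slider": 1
      },
      "element_ids": ["scene", "intro", "activities", "tension", "unwind_video"]
    }
  ]
}
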