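[
  {
    "recipe_id": "minced_pork_10pct",
    "variants": [
      {
        "weight": 1,
        "components": [
          {"ref": "pork_lean_summer", "proportion": 0.92},
          {"ref": "pork_fat_summer", "proportion": 0.08}
        ]
      }
    ]
  },
  {
    "recipe_id": "omelette",
    "variants": [
      {
        "weight": 0.7,
        "components": [
          {"ref": "egg_whole", "proportion": 0.8},
          {"ref": "milk_whole", "proportion": 0.15},
          {"ref": "butter_spreadable", "proportion": 0.05}
        ]
      },
      {
        "weight": 0.3,
        "components": [
          {"ref": "egg_whole", "proportion": 0.8},
          {"ref": "milk_whole", "proportion": 0.1},
          {"ref": "cream", "proportion": 0.1}
        ]
      }
    ]
  },
  {
    "recipe_id": "cream_sauce",
    "variants": [
      {
        "weight": 1,
        "components": [
          {"ref": "cream", "proportion": 0.5},
          {"ref": "milk_whole", "proportion": 0.5}
        ]
      }
    ]
  },
  {
    "recipe_id": "chicken_dinner",
    "variants": [
      {
        "weight": 1,
        "components": [
          {"ref": "chicken_thigh_with_skin", "proportion": 0.6},
          {"ref": "cream_sauce", "proportion": 0.4}
        ]
      }
    ]
  }
]
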