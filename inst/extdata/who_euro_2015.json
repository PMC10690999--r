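{
  "model_name": "who_euro_2015",
  "version": "First Edition (2015)",
  "comment": "WHO Regional Office for Europe nutrient profile model, First Edition (2015). All maxima are per 100 g (foods) or per 100 ml (beverages); energy in kcal, other nutrients in g. permission_mode: never_permitted = marketing to children never permitted regardless of composition; always_permitted = permitted without compositional conditions; threshold_evaluated = permitted only if no maximum is exceeded and no forbidden sweetener is present.",
  "categories": [
    "confectionery", "cakes_biscuits", "savoury_snacks", "juices",
    "milk_drinks", "energy_drinks", "other_beverages", "edible_ices",
    "breakfast_cereals", "yoghurts_cream", "cheese", "ready_made",
    "butter_fats_oils", "bread", "pasta_rice_grains", "fresh_meat_fish",
    "processed_meat_fish", "fresh_fruit_veg", "processed_fruit_veg",
    "sauces_dips"
  ],
  "rules": [
    {
      "category_code": "confectionery",
      "label": "Chocolate and sugar confectionery, energy bars, sweet toppings and desserts",
      "permission_mode": "never_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "cakes_biscuits",
      "label": "Cakes, sweet biscuits and pastries; other sweet bakery wares; dry mixes for making such",
      "permission_mode": "never_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "savoury_snacks",
      "label": "Savoury snacks",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_sugars_g": 10, "salt_g": 0.1},
      "forbid_added_sugars": true,
      "forbid_nss": true
    },
    {
      "category_code": "juices",
      "label": "Juices (fruit and vegetable juices, smoothies, nectars)",
      "permission_mode": "never_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "milk_drinks",
      "label": "Milk drinks",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 2.5},
      "forbid_added_sugars": true,
      "forbid_nss": true
    },
    {
      "category_code": "energy_drinks",
      "label": "Energy drinks",
      "permission_mode": "never_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "other_beverages",
      "label": "Other beverages (soft drinks, waters and all other drinks)",
      "permission_mode": "threshold_evaluated",
      "maxima": {},
      "forbid_added_sugars": true,
      "forbid_nss": true,
      "comment": "Permitted only when free of added sugars and non-sugar sweeteners; no numeric maxima."
    },
    {
      "category_code": "edible_ices",
      "label": "Edible ices and ice cream",
      "permission_mode": "never_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "breakfast_cereals",
      "label": "Breakfast cereals",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 10, "total_sugars_g": 15, "salt_g": 1.6},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "yoghurts_cream",
      "label": "Yoghurts, sour milk, cream and other similar foods",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 2.5, "saturated_fat_g": 2, "total_sugars_g": 10, "salt_g": 0.2},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "cheese",
      "label": "Cheese",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 20, "salt_g": 1.3},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "ready_made",
      "label": "Ready-made and convenience foods and composite dishes",
      "permission_mode": "threshold_evaluated",
      "maxima": {"energy_kcal": 225, "total_fat_g": 10, "saturated_fat_g": 4, "total_sugars_g": 10, "salt_g": 1},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "butter_fats_oils",
      "label": "Butter and other fats and oils",
      "permission_mode": "threshold_evaluated",
      "maxima": {"saturated_fat_g": 20, "trans_fat_g": 1, "salt_g": 1.3},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "bread",
      "label": "Bread, bread products and crisp breads",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 10, "total_sugars_g": 10, "salt_g": 1.2},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "pasta_rice_grains",
      "label": "Fresh or dried pasta, rice and grains",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 10, "total_sugars_g": 10, "salt_g": 1.2},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "fresh_meat_fish",
      "label": "Fresh and frozen meat, poultry, fish and similar",
      "permission_mode": "always_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "processed_meat_fish",
      "label": "Processed meat, poultry, fish and similar",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 20, "salt_g": 1.7},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "fresh_fruit_veg",
      "label": "Fresh and frozen fruit, vegetables and legumes",
      "permission_mode": "always_permitted",
      "maxima": {},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "processed_fruit_veg",
      "label": "Processed fruit, vegetables and legumes",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 5, "total_sugars_g": 10, "salt_g": 1},
      "forbid_added_sugars": false,
      "forbid_nss": false
    },
    {
      "category_code": "sauces_dips",
      "label": "Sauces, dips and dressings",
      "permission_mode": "threshold_evaluated",
      "maxima": {"total_fat_g": 10, "total_sugars_g": 10, "salt_g": 1},
      "forbid_added_sugars": false,
      "forbid_nss": false
    }
  ]
}
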