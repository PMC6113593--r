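{
  "schema_version": "1.0",
  "comment": "Recipes of the three chemically measured benchmark dishes. Ingredient lists and preparation methods are as published; ingredient WEIGHTS are synthetic placeholders (the source reports none).",
  "recipes": [
    {
      "dish": "garlic puree cooked pork leg",
      "dish_type": "cooked",
      "method": "steam",
      "ingredients": [
        {"ingredient": "pork leg", "weight_g": 500, "auxiliary": false},
        {"ingredient": "garlic", "weight_g": 20, "auxiliary": true},
        {"ingredient": "scallions", "weight_g": 10, "auxiliary": true},
        {"ingredient": "pepper", "weight_g": 2, "auxiliary": true}
      ]
    },
    {
      "dish": "dry-fried string beans",
      "dish_type": "cooked",
      "method": "stir-fry",
      "ingredients": [
        {"ingredient": "string beans", "weight_g": 400, "auxiliary": false},
        {"ingredient": "minced pork", "weight_g": 80, "auxiliary": false},
        {"ingredient": "dried chilies", "weight_g": 5, "auxiliary": true},
        {"ingredient": "garlic", "weight_g": 10, "auxiliary": true},
        {"ingredient": "scallions", "weight_g": 10, "auxiliary": true}
      ]
    },
    {
      "dish": "roast lamb",
      "dish_type": "cooked",
      "method": "roast",
      "ingredients": [
        {"ingredient": "lamb", "weight_g": 450, "auxiliary": false},
        {"ingredient": "onion", "weight_g": 100, "auxiliary": false},
        {"ingredient": "cumin", "weight_g": 5, "auxiliary": true},
        {"ingredient": "vegetable oil", "weight_g": 30, "auxiliary": false}
      ]
    }
  ]
}
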