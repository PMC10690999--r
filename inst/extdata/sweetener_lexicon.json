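{
  "comment": "Default English-language sweetener lexicon. added_sugar_terms and nss_terms are matched case-insensitively as whole tokens/phrases after punctuation normalization; negative_context phrases are removed from the text before matching so that e.g. 'no added sugar' or 'sugar snap peas' cannot trigger the 'sugar' term.",
  "added_sugar_terms": [
    "sugar", "sugars", "brown sugar", "cane sugar", "raw sugar",
    "icing sugar", "invert sugar", "invert sugar syrup", "coconut sugar",
    "demerara sugar", "muscovado sugar", "sucrose", "glucose", "dextrose",
    "fructose", "maltose", "lactose syrup", "glucose syrup",
    "glucose fructose syrup", "fructose glucose syrup", "corn syrup",
    "high fructose corn syrup", "corn syrup solids", "golden syrup",
    "maple syrup", "agave syrup", "agave nectar", "rice syrup",
    "brown rice syrup", "malt syrup", "barley malt extract", "malt extract",
    "honey", "molasses", "treacle", "caramel syrup",
    "fruit juice concentrate", "concentrated fruit juice", "fruit syrup",
    "date syrup", "maltodextrin syrup"
  ],
  "nss_terms": [
    "aspartame", "sucralose", "saccharin", "sodium saccharin",
    "acesulfame k", "acesulfame potassium", "acesulfame",
    "cyclamate", "sodium cyclamate", "calcium cyclamate",
    "steviol glycosides", "stevia", "stevia extract", "rebaudioside a",
    "neotame", "advantame", "thaumatin", "neohesperidine dc",
    "neohesperidine dihydrochalcone", "aspartame acesulfame salt",
    "sorbitol", "mannitol", "xylitol", "maltitol", "maltitol syrup",
    "isomalt", "lactitol", "erythritol",
    "e420", "e421", "e950", "e951", "e952", "e953", "e954", "e955",
    "e956", "e957", "e959", "e960", "e961", "e962", "e964", "e965",
    "e966", "e967", "e968", "e969"
  ],
  "negative_context": [
    "no added sugar", "no added sugars", "without added sugar",
    "without added sugars", "no sugar added", "sugar free", "sugarfree",
    "contains no sugar", "unsweetened", "sugar snap peas", "sugar snap"
  ]
}
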