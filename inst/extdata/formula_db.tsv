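name	formula	class
succinate	C4H6O4	carboxylic acid
malate	C4H6O5	carboxylic acid
fumarate	C4H4O4	carboxylic acid
lactate	C3H6O3	carboxylic acid
acetate	C2H4O2	carboxylic acid
propionate	C3H6O2	carboxylic acid
butyrate	C4H8O2	carboxylic acid
pyruvate	C3H4O3	carboxylic acid
formate	CH2O2	carboxylic acid
arginine	C6H14N4O2	amino acid
ornithine	C5H12N2O2	amino acid
histidine	C6H9N3O2	amino acid
cysteine	C3H7NO2S	amino acid
glutamate	C5H9NO4	amino acid
leucine	C6H13NO2	amino acid
isoleucine	C6H13NO2	amino acid
alanine	C3H7NO2	amino acid
glycine	C2H5NO2	amino acid
xanthine	C5H4N4O2	nucleobase
hypoxanthine	C5H4N4O	nucleobase
uracil	C4H4N2O2	nucleobase
adenine	C5H5N5	nucleobase
glucose	C6H12O6	carbohydrate
sorbitol	C6H14O6	carbohydrate
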