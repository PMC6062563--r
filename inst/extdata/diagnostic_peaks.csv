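author,mz,annotation,formula,adduct,in_table,note
A,207.0654,Citropen/Scoparone - natural plant metabolite,C11H10O4,M+H,1,
A,273.0289,,,,1,unannotated
A,283.1178,Bis(2-methoxyethyl) phthalate,C14H18O6,M+H,1,
A,291.0842,,,,1,unannotated
A,305.0996,,,,1,unannotated
A,327.0782,Triphenyl phosphate,C18H15O4P,M+H,1,
A,344.1049,,,,1,unannotated
A,349.0602,,C14H12N4O5S,M+H,1,
B,113.9639,,,,1,unannotated; possibly inorganic cluster ion
B,130.5259,,,,1,unannotated; fractional m/z carried as empirical marker
B,230.9904,Citric acid (Potassium adduct),C6H8O7,M+K,1,
B,243.0993,,C11H10N6O,M+H,1,
B,258.0286,,,,1,unannotated
B,328.1794,,C14H25N5O2S,M+H,1,
B,364.9642,,,,1,unannotated; possibly inorganic cluster ion
B,377.2091,,C21H24N6O,M+H,1,
B,272.0655,,,,0,schematic-figure ion; possibly the same feature as 273.0289 or a typo for it; not assigned a formula
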