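# Curated hydrocarbonoclastic bacteria (HCB) genera.
# Specialist or facultative hydrocarbon degraders reported from
# hydrocarbon-polluted marine environments, hydrocarbon-stimulated
# enrichments, or isolates/MAGs with demonstrated catabolic activity.
# One genus per line; extend freely (matching is case-insensitive at the
# genus rank).
Pseudoalteromonas
Sulfitobacter
Psychrobacter
Colwellia
Glaciecola
Alteromonas
Thalassospira
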