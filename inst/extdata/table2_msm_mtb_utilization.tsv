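source	type	mtb_call	msm_call	differential
2-oxoglutarate	carbon	growth	NA	false
Oxalomalate	carbon	growth	NA	false
Acetate	carbon	growth	growth	false
Propanoate	carbon	no_growth	growth	true
Acetoacetic acid	carbon	growth	NA	false
Pyruvate	carbon	growth	growth	false
Adenosine	carbon	no_growth	no_growth	false
D-serine	carbon	growth	no_growth	true
D-alanine	carbon	growth	growth	false
D-tagatose	carbon	no_growth	NA	false
L-alanine	carbon	growth	growth	false
D-trehalose	carbon	growth	growth	false
L-asparagine	carbon	growth	growth	false
Tween 20	carbon	growth	growth	false
Butyrate	carbon	growth	growth	false
Tween 40	carbon	growth	growth	false
Caproic acid	carbon	growth	growth	false
Tween 80	carbon	growth	growth	false
Citrate	carbon	growth	growth	false
D-fructose-6-phosphate	carbon	growth	growth	false
D-glucose-6-phosphate	carbon	growth	growth	false
D-glucose	carbon	growth	growth	false
L-glutamate	carbon	growth	growth	false
L-glutamine	carbon	growth	growth	false
Glycerol	carbon	growth	growth	false
Glycine	carbon	growth	NA	false
L-lactate	carbon	growth	growth	false
D-malate	carbon	no_growth	growth	true
L-malate	carbon	growth	growth	false
D-mannose	carbon	no_growth	growth	true
Methyl-pyruvate	carbon	growth	growth	false
Mono methyl-succinate	carbon	growth	growth	false
N-acetyl-glucosamine	carbon	no_growth	growth	true
L-Alanine	nitrogen	growth	growth	false
Allantoin	nitrogen	no_growth	growth	true
L-Asparagine	nitrogen	growth	growth	false
L-Aspartic acid	nitrogen	no_growth	growth	true
L-Cysteine	nitrogen	growth	growth	false
D-Galactosamine	nitrogen	growth	growth	false
D-Glucosamine	nitrogen	no_growth	growth	true
L-Glutamic acid	nitrogen	growth	growth	false
L-Glutamine	nitrogen	growth	growth	false
L-Ornithine	nitrogen	growth	growth	false
D-Serine	nitrogen	growth	growth	false
L-Serine	nitrogen	growth	growth	false
L-Threonine	nitrogen	no_growth	growth	true
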