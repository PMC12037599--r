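name	hemisphere
bankssts	left
caudalanteriorcingulate	left
caudalmiddlefrontal	left
cuneus	left
entorhinal	left
frontalpole	left
fusiform	left
inferiorparietal	left
inferiortemporal	left
insula	left
isthmuscingulate	left
lateraloccipital	left
lateralorbitofrontal	left
lingual	left
medialorbitofrontal	left
middletemporal	left
paracentral	left
parahippocampal	left
parsopercularis	left
parsorbitalis	left
parstriangularis	left
pericalcarine	left
postcentral	left
posteriorcingulate	left
precentral	left
precuneus	left
rostralanteriorcingulate	left
rostralmiddlefrontal	left
superiorfrontal	left
superiorparietal	left
superiortemporal	left
supramarginal	left
temporalpole	left
transversetemporal	left
bankssts	right
caudalanteriorcingulate	right
caudalmiddlefrontal	right
cuneus	right
entorhinal	right
frontalpole	right
fusiform	right
inferiorparietal	right
inferiortemporal	right
insula	right
isthmuscingulate	right
lateraloccipital	right
lateralorbitofrontal	right
lingual	right
medialorbitofrontal	right
middletemporal	right
paracentral	right
parahippocampal	right
parsopercularis	right
parsorbitalis	right
parstriangularis	right
pericalcarine	right
postcentral	right
posteriorcingulate	right
precentral	right
precuneus	right
rostralanteriorcingulate	right
rostralmiddlefrontal	right
superiorfrontal	right
superiorparietal	right
superiortemporal	right
supramarginal	right
temporalpole	right
transversetemporal	right
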