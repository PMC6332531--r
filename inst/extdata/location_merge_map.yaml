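# Raw subcellular compartment label -> major location.
# Golgi, ER, endosome, peroxisome, lysosome, vacuole and vesicles are
# merged into one secretory-pathway label; mitochondria is kept as its
# own major location.
extracellular: extracellular
plasma membrane: membrane
cytoplasm: cytoplasm
mitochondria: mitochondria
Golgi apparatus: secretory-pathway
endoplasmic reticulum: secretory-pathway
endosome: secretory-pathway
peroxisome: secretory-pathway
lysosome: secretory-pathway
vacuole: secretory-pathway
vesicles: secretory-pathway
nucleus: nucleus
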