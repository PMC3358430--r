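trait	trait_class
Type 1 diabetes	other
Crohn's disease	other
Ulcerative colitis	other
Mean corpuscular volume	blood
White blood cell count	blood
Hemoglobin levels	blood
Platelet counts	blood
Schizophrenia	brain
Parkinson's disease	brain
Alzheimer's disease (late onset)	brain
Major depressive disorder	brain
Body mass index	other
Height	other
Smoking behavior	brain
Eye color	other
Liver enzyme levels	other
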