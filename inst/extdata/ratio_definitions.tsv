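ratio	part	metabolite
SCFA/BCFA	numerator	Acetic acid
SCFA/BCFA	numerator	Propionic acid
SCFA/BCFA	numerator	Valeric acid
SCFA/BCFA	numerator	Caproic acid
SCFA/BCFA	denominator	Isotridecanoic acid
SCFA/BCFA	denominator	Isomyristic acid
SCFA/BCFA	denominator	Isopentadecanoic acid
SCFA/BCFA	denominator	Anteisopentadecanoic acid
SCFA/BCFA	denominator	Iso/Anteisopalmitic acid
SCFA/BCFA	denominator	Isomargaric acid
SCFA/BCFA	denominator	Anteisomargaric acid
MUFA/PUFA	numerator	Linoleic Acid/Oleic Acid
MUFA/PUFA	denominator	Arachidonic Acid
MUFA/PUFA	denominator	Eicosatrienoic Acid
MUFA/PUFA	denominator	Docosahexaenoic Acid
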