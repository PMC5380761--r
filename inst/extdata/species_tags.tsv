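code	clade	subclade
PHYPA	outgroup
SELML	outgroup
PHODC	monocot
MUSAC	monocot
ORYSJ	monocot	Poaceae
ORYSI	monocot	Poaceae
BRADI	monocot	Poaceae
SETIT	monocot	Poaceae
MAIZE	monocot	Poaceae
SORBI	monocot	Poaceae
SOLTU	dicot	Solanaceae
SOLLC	dicot	Solanaceae
VITVI	dicot
GLYMA	dicot
CAJCA	dicot
LOTJA	dicot
MEDTR	dicot
PRUPE	dicot
MALDO	dicot
CUCSA	dicot
CUCME	dicot
RICCO	dicot
JATCU	dicot
MANES	dicot
POPTR	dicot
GOSRA	dicot
THECC	dicot
CARPA	dicot	Brassicales
ARALY	dicot	Brassicaceae
ARATH	dicot	Brassicaceae
BRARA	dicot	Brassicaceae
EUTSA	dicot	Brassicaceae
SCHPA	dicot	Brassicaceae
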