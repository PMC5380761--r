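(PHYPA,(SELML,((PHODC,(MUSAC,((ORYSJ,ORYSI),(BRADI,(SETIT,(MAIZE,SORBI)))))),((SOLTU,SOLLC),(VITVI,(((((GLYMA,CAJCA),(LOTJA,MEDTR)),((PRUPE,MALDO),(CUCSA,CUCME))),(((RICCO,JATCU),MANES),POPTR)),((GOSRA,THECC),(CARPA,((ARALY,ARATH),(BRARA,(EUTSA,SCHPA)))))))))));
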