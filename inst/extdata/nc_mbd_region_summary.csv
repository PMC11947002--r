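region,population,visits_total,visits_substance,visits_mood,visits_anxiety
Mountains,1099538,760040,533235,208913,226600
Piedmont,5942142,3391613,2335924,803011,806742
Coast,2803653,1797447,1241902,409915,417826
North Carolina,9845333,5949100,4111061,1421839,1451168
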