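{"heterotypic":{"phenotype":{"K":0.049,"Kb":3.57,"KGs0":0.713,"KGt0":0.687,"Kstr":0.000714,"Kstrd":0.00564,"a":0.046,"b":0.038,"g":0.018},"drug":{},"schedule":{"start":[],"end":[],"conc":[]},"total":5000}}
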