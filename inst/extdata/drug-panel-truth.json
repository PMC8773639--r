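{"heterotypic-cisplatin-continuous":{"phenotype":{"K":0.033,"Kb":0,"KGs0":1.033,"KGt0":0.976,"Kstr":0.00059,"Kstrd":0,"a":0,"b":0.04,"g":0.034},"drug":{"Sdrug":108,"AUCs5":239,"AUCs95":1153,"SCALEs":8.61,"AUCt5":233,"AUCt95":1201,"SCALEt":5.79},"schedule":{"start":0,"end":6,"conc":5},"total":5000},"heterotypic-cisplatin-intermittent":{"phenotype":{"K":0.033,"Kb":0,"KGs0":1.033,"KGt0":0.976,"Kstr":0.00059,"Kstrd":0,"a":0,"b":0.04,"g":0.034},"drug":{"Sdrug":108,"AUCs5":239,"AUCs95":1153,"SCALEs":8.61,"AUCt5":233,"AUCt95":1201,"SCALEt":5.79},"schedule":{"start":0,"end":2,"conc":5},"total":5000}}
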