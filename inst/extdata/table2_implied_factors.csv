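name,currency,price_year,implied_factor
Bosentan monohydrate,AUD,2004,1.1365208
Peginterferon alfa 2a,GBP,2005,1.6600153
Conjugated vaccine,GBP,2001,1.7618529
Ezetimibe,GBP,2006,1.6286282
Sirolimus,GBP,2003,1.233867
Interferon beta-1a,CAD,2002,1.1040637
Ibandronate,GBP,2003,1.2338684
Rizatriptan,CAD,2002,1.0846385
Linezolid,CAD,2001,1.1532262
Rivastigmine,CAD,2004,1.0431425
Rosiglitazone,GBP,2000,1.7806521
Oseltamivir,USD,2006,0.8455128
Clopidogrel,USD,2002,1.1401797
Memantine,USD,2005,0.8048828
Risperidone,USD,2006,1.018287
Atomoxetine,GBP,2004,1.687385
Atorvastatin,EUR,2005,1.3663169
Orlistat,EUR,2003,1.3821996
Natalizumab,EUR,2005,1.1361864
Oxaliplatin,GBP,2003,1.682204
Rosuvastatin,EUR,2006,1.3523799
Trastuzumab,EUR,2005,1.3663166
Cinacalcet,GBP,2004,1.6873978
Sitagliptin,EUR,2006,1.3621833
Rimonabant,USD,2006,1.0182871
Pimecrolimus,CAD,2002,1.1040637
HPV vaccine,CHF,2006,1.0338396
Fulvestrant,EUR,2007,1.1956793
Erlotinib,USD,2007,0.866201
Eplerenone,USD,2001,1.1532261
Raltegravir,CHF,2007,1.0266816
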