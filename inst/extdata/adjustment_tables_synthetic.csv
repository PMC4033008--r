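table,currency,year,value
deflator,CHF,2000,92.34102243269047
deflator,CHF,2001,93.07975061215200
deflator,CHF,2002,93.82438861704921
deflator,CHF,2003,94.57498372598560
deflator,CHF,2004,95.33158359579349
deflator,CHF,2005,96.09423626455984
deflator,CHF,2006,96.86299015467631
deflator,CHF,2007,97.63789407591372
deflator,CHF,2008,98.41899722852104
deflator,CHF,2009,99.20634920634922
deflator,CHF,2010,100.00000000000000
deflator,GBP,2000,78.11984017257274
deflator,GBP,2001,80.07283617688704
deflator,GBP,2002,82.07465708130921
deflator,GBP,2003,84.12652350834193
deflator,GBP,2004,86.22968659605047
deflator,GBP,2005,88.38542876095174
deflator,GBP,2006,90.59506447997552
deflator,GBP,2007,92.85994109197489
deflator,GBP,2008,95.18143961927426
deflator,GBP,2009,97.56097560975611
deflator,GBP,2010,100.00000000000000
deflator,AUD,2000,74.40939148967249
deflator,AUD,2001,76.64167323436267
deflator,AUD,2002,78.94092343139356
deflator,AUD,2003,81.30915113433535
deflator,AUD,2004,83.74842566836543
deflator,AUD,2005,86.26087843841638
deflator,AUD,2006,88.84870479156888
deflator,AUD,2007,91.51416593531594
deflator,AUD,2008,94.25959091337543
deflator,AUD,2009,97.08737864077671
deflator,AUD,2010,100.00000000000000
deflator,CAD,2000,80.44351556773952
deflator,CAD,2001,82.21327291022979
deflator,CAD,2002,84.02196491425485
deflator,CAD,2003,85.87044814236846
deflator,CAD,2004,87.75959800150058
deflator,CAD,2005,89.69030915753359
deflator,CAD,2006,91.66349595899932
deflator,CAD,2007,93.68009287009731
deflator,CAD,2008,95.74105491323945
deflator,CAD,2009,97.84735812133071
deflator,CAD,2010,100.00000000000000
deflator,USD,2000,78.88609052210116
deflator,USD,2001,80.77935669463160
deflator,USD,2002,82.71806125530276
deflator,USD,2003,84.70329472543003
deflator,USD,2004,86.73617379884034
deflator,USD,2005,88.81784197001251
deflator,USD,2006,90.94947017729281
deflator,USD,2007,93.13225746154784
deflator,USD,2008,95.36743164062500
deflator,USD,2009,97.65625000000000
deflator,USD,2010,100.00000000000000
deflator,EUR,2000,82.84344680012732
deflator,EUR,2001,84.41747228932974
deflator,EUR,2002,86.02140426282699
deflator,EUR,2003,87.65581094382070
deflator,EUR,2004,89.32127135175328
deflator,EUR,2005,91.01837550743659
deflator,EUR,2006,92.74772464207788
deflator,EUR,2007,94.50993141027735
deflator,EUR,2008,96.30562010707261
deflator,EUR,2009,98.13542688910698
deflator,EUR,2010,100.00000000000000
ppp,CHF,2010,1.00000000000000
ppp,GBP,2010,1.65000000000000
ppp,CAD,2010,1.25000000000000
ppp,USD,2010,1.30000000000000
ppp,EUR,2010,1.55000000000000
ppp,AUD,2010,0.95181829563856
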