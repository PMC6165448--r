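band,low,high,assignment,aux
3500-3200,3200,3500,O-H and N-H symmetric stretching (alcohols and amide/proteins),FALSE
3100-3020,3020,3100,vinyl C-H stretching of lipids (olefinic groups),FALSE
2950-2920,2920,2950,methyl asymmetric C-H stretching of lipids,FALSE
2852,2852,2852,methylene symmetric C-H stretching of lipids,FALSE
1744,1744,1744,C=O stretching of triglyceride ester carbonyl,FALSE
1627,1627,1627,amide I C=O stretching of proteins (beta-sheet region),FALSE
1541,1541,1541,amide II N-H bending combined with C-N stretching of proteins,FALSE
1450,1450,1450,C-H asymmetric vibration of protein moieties,FALSE
1395,1395,1395,C-H symmetric vibration of protein moieties,FALSE
1240,1240,1240,P=O asymmetric stretching (phospholipids or nucleic acids),FALSE
1170-1154,1154,1170,C-O stretching of proteins and triglycerides,FALSE
1117,1117,1117,C-H bending and deformation of fatty acids,FALSE
1040-1020,1020,1040,carbohydrate moieties (glycogen indicator),FALSE
966,966,966,trans CH=CH out-of-plane deformation,FALSE
870,870,870,para-disubstituted aromatic derivatives,FALSE
717,717,717,cis -CH=CH- out-of-plane bending of unsaturated fatty acids,TRUE
1083,1083,1083,P=O symmetric stretching (phospholipids or nucleic acids),TRUE
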