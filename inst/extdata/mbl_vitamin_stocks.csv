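vitamin_id,name,stock_molarity
ALA,Lipoic acid,4.85e-7
B1,Thiamine hydrochloride,2.97e-7
B1-PP,Thiamine pyrophosphate,2.17e-7
B2,Riboflavin,2.66e-7
B3,Nicotinic acid,8.12e-7
B3-NAD,Nicotinamide adenine dinucleotide,1.51e-7
B5,Calcium d-pantothenate,4.20e-7
B6,Pyridoxine hydrochloride,4.86e-7
B7,D-Biotin,1.23e-7
B9,Folic acid,2.27e-7
B9-PABA,4-aminobenzoic acid,7.29e-7
C,L-ascorbic acid,5.68e-7
B12,Cyanocobalamin,7.38e-9
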