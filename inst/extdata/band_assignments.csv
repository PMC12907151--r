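position,allocation,reference_note
621,Phosphate backbone (DNA/RNA),nucleic_acid
643,Tyrosine (ring breathing),protein
672,Phosphate backbone (DNA/RNA),nucleic_acid
719,Cholesterol (steroid ring breathing),lipid
751,Tryptophan (indole ring vibrations),protein
781,Phenylalanine,protein
837,"Proteins (Amide III, in-plane N-H bending and C-N stretching)",protein
872,Saccharides,carbohydrate
889,Glycogen,carbohydrate
936,Proline,protein
972,Phospholipids,lipid
1001,Phenylalanine,protein
1031,Lipids,lipid
1065,C-C Stretching in lipids,lipid
1111,C-C Stretching in lipids,lipid
1125,Desoxyribose (DNA/RNA),nucleic_acid
1143,Lipids,lipid
1156,Proteins (Amide III),protein
1172,Proteins (Amide III),protein
1207,Tryptophan,protein
1259,Proteins (Amide III),protein
1301,CH2 Twisting in lipids,lipid
1314,CH2 Twisting and Wagging in lipids,lipid
1326,Guanine (DNA/RNA),nucleic_acid
1338,Collagen fibers,protein
1369,CH3 Deformation in lipids,lipid
1403,COO- groups (Carboxylates in amino acids),protein
1445,CH2 Deformation in lipids and proteins,lipid
1512,NADH,cofactor
1524,Chromophores like cytochromes,cofactor
1553,Proteins (Amide II),protein
1582,Chromophores like cytochromes,cofactor
1618,Proteins (Amide I),protein
1657,"Proteins (Amide I, C=O Stretching)",protein
1745,Ester C=O Stretching (Triglycerides in lipids),lipid
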