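"name","smiles","DeltaEpsilonC","MMFF_29","SssssCcount","T_2_2_1","SdsCHE-index","SdssCE-index","T_2_2_2","H-AcceptorCount","T_O_O_3","T_T_N_4","SssssCE-index","MW","HBD","HBA"
"methane","C",0,0,0,0,0,0,0,0,0,0,0,16.043,0,0
"ethane","CC",0,0,0,0,0,0,0,0,0,0,0,30.07,0,0
"ethene","C=C",0,0,0,1,0,0,0,0,0,0,0,28.054,0,0
"propene","C=CC",0.25,0,0,1,1.75,0,0,0,0,0,0,42.081,0,0
"isobutylene","CC(=C)C",0.25,0,0,1,0,1.1666666667,0,0,0,0,0,56.108,0,0
"butadiene","C=CC=C",0,0,0,3,3.2777777778,0,2,0,0,0,0,54.092,0,0
"neopentane","CC(C)(C)C",0,0,1,0,0,0,0,0,0,0,0.5,72.151,0,0
"benzene","c1ccccc1",0,0,0,6,0,0,6,0,0,0,0,78.114,0,0
"toluene","Cc1ccccc1",0.25,0,0,6,0,0,6,0,0,0,0,92.141,0,0
"phenol","Oc1ccccc1",0,1,0,6,0,0,6,1,0,0,0,94.113,1,1
"ethanol","CCO",0,0,0,0,0,0,0,1,0,0,0,46.069,1,1
"glycol","OCCO",0,0,0,0,0,0,0,2,1,0,0,62.068,2,2
"glycerol","OCC(O)CO",0,0,0,0,0,0,0,3,2,0,0,92.094,3,3
"acetone","CC(C)=O",0.25,0,0,1,0,0.1666666667,0,1,0,0,0,58.08,0,1
"acetic_acid","CC(=O)O",0.25,0,0,1,0,-0.8333333333,0,2,0,0,0,60.052,1,2
"acetamide","CC(=O)N",0.25,0,0,1,0,-0.3333333333,0,1,0,0,0,59.068,2,2
"acrolein","C=CC=O",0,0,0,3,1.8333333333,0,2,1,0,0,0,56.064,0,1
"pyridine","c1ccncc1",0,0,0,6,0,0,6,1,0,0,0,79.102,0,1
"pyrrole","c1cc[nH]c1",0,0,0,3,0,0,3,0,0,0,0,67.091,1,1
"aniline","Nc1ccccc1",0,0,0,6,0,0,6,1,0,1,0,93.129,2,1
"aminopyridine","Nc1ccncc1",0,0,0,6,0,0,6,2,0,1,0,94.117,2,2
"anisole","COc1ccccc1",0.25,0,0,6,0,0,6,1,0,0,0,108.14,0,1
"xanthone","O=C1c2ccccc2Oc2ccccc21",0,0,0,15,0,0,20,2,0,0,0,196.205,0,2
"caged_enone","CC1(C)C2CC3CC1C(=O)C3(O)C2",0.25,0,2,1,0,0.1493055556,0,2,1,0,-0.7488425926,180.247,1,2
"tbutyl_phenol","CC(C)(C)c1ccc(O)cc1",0.25,1,1,6,0,0,6,1,0,0,0.1743055556,150.221,1,1
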