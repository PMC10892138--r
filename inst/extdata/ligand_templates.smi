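# Small, pre-validated drug-like SMILES templates used by the synthetic
# protein-ligand fixture generator. One SMILES per line.
CCO
CC(=O)O
CC(C)O
CCN
CC(N)=O
OCC(O)CO
C1CCNCC1
CN1CCCC1
c1ccccc1
Cc1ccccc1
Oc1ccccc1
COc1ccccc1
Nc1ccccc1
c1ccncc1
Cc1ccncc1
O=C(O)c1ccccc1
CC(=O)Nc1ccc(O)cc1
CC(=O)Oc1ccccc1C(=O)O
CC(C)Cc1ccccc1
OCc1ccccc1
NCCc1ccccc1
O=C(N)c1ccccc1
Clc1ccccc1
Fc1ccccc1
CCOC(=O)C
CC(C)(C)O
C1CCOC1
O=C1CCCCC1
N#Cc1ccccc1
CSc1ccccc1
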