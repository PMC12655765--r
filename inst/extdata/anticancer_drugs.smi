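# Small anticancer compounds used as structural fixtures.
# SMILES are the public structures of the named drugs; each was validated
# against the drug's known molecular formula.
Nc1ccn([C@@H]2O[C@H](CO)[C@@H](O)[C@@H]2O)c(=O)n1	cytarabine
Nc1ccn([C@@H]2O[C@H](CO)[C@@H](O)C2(F)F)c(=O)n1	gemcitabine
O=C(NCCCl)N(CCCl)N=O	carmustine
O=C(NC1CCCCC1)N(CCCl)N=O	lomustine
CN(CCCl)CCCl	mechlorethamine
O=c1[nH]cc(F)c(=O)[nH]1	fluorouracil
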