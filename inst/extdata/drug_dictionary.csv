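synonym,concept_id
CYCLOSPORINE,CSA
CICLOSPORIN,CSA
CYCLOSPORIN A,CSA
NEORAL,CSA
SANDIMMUNE,CSA
GENGRAF,CSA
RESTASIS,CSA
TACROLIMUS,TAC
PROGRAF,TAC
MYCOPHENOLATE MOFETIL,MMF
CELLCEPT,MMF
PREDNISONE,PRED
DELTASONE,PRED
ASPIRIN,ASA
ACETYLSALICYLIC ACID,ASA
PARACETAMOL,PARA
ACETAMINOPHEN,PARA
TYLENOL,PARA
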