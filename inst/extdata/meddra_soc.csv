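soc_code,soc_name
10015919,Eye disorders
10038359,Renal and urinary disorders
10047065,Vascular disorders
10029205,Nervous system disorders
10017947,Gastrointestinal disorders
10021881,Infections and infestations
10019805,Hepatobiliary disorders
10007541,Cardiac disorders
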