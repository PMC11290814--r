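pt_code,pt_name,soc_code
10055890,Scleral hyperaemia,10015919
10015946,Eye irritation,10015919
10047513,Vision blurred,10015919
10062237,Renal impairment,10038359
10005483,Blood creatinine increased,10038359
10020772,Hypertension,10047065
10044565,Tremor,10029205
10019211,Headache,10029205
10018286,Gingival hyperplasia,10017947
10028813,Nausea,10017947
10012735,Diarrhoea,10017947
10021789,Infection,10021881
10019851,Hepatotoxicity,10019805
10023126,Jaundice,10019805
10007554,Cardiac failure,10007541
10028596,Myocardial infarction,10007541
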