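pt	soc
Diarrhoea	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Stomatitis	Gastrointestinal disorders
Oral pain	Gastrointestinal disorders
Fatigue	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Oedema peripheral	General disorders and administration site conditions
Death	General disorders and administration site conditions
Decreased appetite	Metabolism and nutrition disorders
Dehydration	Metabolism and nutrition disorders
Hypertension	Vascular disorders
Dysgeusia	Nervous system disorders
Ageusia	Nervous system disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Hypothyroidism	Endocrine disorders
Thyroid atrophy	Endocrine disorders
Thyroid disorder	Endocrine disorders
Palmar-plantar erythrodysaesthesia syndrome	Skin and subcutaneous tissue disorders
Yellow skin	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Dry skin	Skin and subcutaneous tissue disorders
Hair colour changes	Skin and subcutaneous tissue disorders
Thrombocytopenia	Blood and lymphatic system disorders
Anaemia	Blood and lymphatic system disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Epistaxis	Respiratory, thoracic and mediastinal disorders
Insomnia	Psychiatric disorders
Diffuse uveal melanocytic proliferation	Eye disorders
Salivary gland fistula	Gastrointestinal disorders
Scrotal inflammation	Reproductive system and breast disorders
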