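Diarrhoea
Nausea
Vomiting
Stomatitis
Fatigue
Asthenia
Pyrexia
Decreased appetite
Hypertension
Dysgeusia
Headache
Dizziness
Hypothyroidism
Palmar-plantar erythrodysaesthesia syndrome
Yellow skin
Rash
Dry skin
Hair colour changes
Thrombocytopenia
Dyspnoea
Epistaxis
Dehydration
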