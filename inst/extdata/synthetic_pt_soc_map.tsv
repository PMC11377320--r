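pt	soc
Thrombocytopenia	Blood and lymphatic system disorders
Anaemia	Blood and lymphatic system disorders
Neutropenia	Blood and lymphatic system disorders
Pancytopenia	Blood and lymphatic system disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Headache	Nervous system disorders
Seizure	Nervous system disorders
Brain edema	Nervous system disorders
Rash	Skin and subcutaneous tissue disorders
Petechiae	Skin and subcutaneous tissue disorders
Platelet count decreased	Investigations
Alanine aminotransferase increased	Investigations
Sepsis	Infections and infestations
Pneumonia	Infections and infestations
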