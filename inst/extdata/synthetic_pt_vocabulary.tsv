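pt	soc
gastrointestinal pain	gastrointestinal disorders
flatulence	gastrointestinal disorders
abdominal distension	gastrointestinal disorders
abdominal discomfort	gastrointestinal disorders
abdominal pain upper	gastrointestinal disorders
vomiting	gastrointestinal disorders
constipation	gastrointestinal disorders
diarrhoea	gastrointestinal disorders
nausea	gastrointestinal disorders
hypophagia	metabolism and nutrition disorders
decreased appetite	metabolism and nutrition disorders
dehydration	metabolism and nutrition disorders
agitation	psychiatric disorders
anxiety	psychiatric disorders
insomnia	psychiatric disorders
asthenia	general disorders and administration site conditions
fatigue	general disorders and administration site conditions
pyrexia	general disorders and administration site conditions
malaise	general disorders and administration site conditions
product taste abnormal	general disorders and administration site conditions
hepatic enzyme increased synthetic	hepatobiliary disorders
jaundice synthetic	hepatobiliary disorders
hepatitis synthetic	hepatobiliary disorders
hypersensitivity	immune system disorders
anaphylactic reaction	immune system disorders
sepsis	infections and infestations
fungal infection	infections and infestations
urinary tract infection	infections and infestations
arthralgia	musculoskeletal and connective tissue disorders
myalgia	musculoskeletal and connective tissue disorders
back pain	musculoskeletal and connective tissue disorders
headache	nervous system disorders
dizziness	nervous system disorders
tremor	nervous system disorders
renal impairment synthetic	renal and urinary disorders
dysuria synthetic	renal and urinary disorders
hypertension synthetic	vascular disorders
flushing synthetic	vascular disorders
dyspnoea	respiratory thoracic and mediastinal disorders
cough	respiratory thoracic and mediastinal disorders
weight decreased	investigations
blood test abnormal synthetic	investigations
fall	injury poisoning and procedural complications
overdose	injury poisoning and procedural complications
rash	skin and subcutaneous tissue disorders
pruritus	skin and subcutaneous tissue disorders
urticaria	skin and subcutaneous tissue disorders
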