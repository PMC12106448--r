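pt	soc
gastrointestinal pain	gastrointestinal disorders
flatulence	gastrointestinal disorders
abdominal distension	gastrointestinal disorders
abdominal discomfort	gastrointestinal disorders
abdominal pain upper	gastrointestinal disorders
vomiting	gastrointestinal disorders
constipation	gastrointestinal disorders
hypophagia	metabolism and nutrition disorders
agitation	psychiatric disorders
anxiety	psychiatric disorders
asthenia	general disorders and administration site conditions
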