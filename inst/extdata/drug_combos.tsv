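alias	components
atripla	EFV,TDF,FTC
complera	RPV,TDF,FTC
stribild	EVG,COBI,TDF,FTC
genvoya	EVG,COBI,TAF,FTC
triumeq	DTG,ABC,3TC
truvada	TDF,FTC
descovy	TAF,FTC
odefsey	RPV,TAF,FTC
epzicom	ABC,3TC
combivir	AZT,3TC
trizivir	AZT,3TC,ABC
kaletra	LPV,RTV
prezcobix	DRV,COBI
evotaz	ATV,COBI
biktarvy	BIC,TAF,FTC
juluca	DTG,RPV
dovato	DTG,3TC
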