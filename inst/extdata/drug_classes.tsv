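code	class	aliases
TDF	NRTI	tenofovir disoproxil fumarate|tenofovir df|viread
TAF	NRTI	tenofovir alafenamide|vemlidy
FTC	NRTI	emtricitabine|emtriva
3TC	NRTI	lamivudine|epivir
ABC	NRTI	abacavir|ziagen
AZT	NRTI	zidovudine|retrovir|zdv
D4T	NRTI	stavudine|zerit
DDI	NRTI	didanosine|videx
EFV	NNRTI	efavirenz|sustiva
RPV	NNRTI	rilpivirine|edurant
NVP	NNRTI	nevirapine|viramune
ETR	NNRTI	etravirine|intelence
DOR	NNRTI	doravirine|pifeltro
ATV	PI	atazanavir|reyataz
DRV	PI	darunavir|prezista
LPV	PI	lopinavir
SQV	PI	saquinavir|invirase
IDV	PI	indinavir|crixivan
NFV	PI	nelfinavir|viracept
FPV	PI	fosamprenavir|lexiva
TPV	PI	tipranavir|aptivus
RAL	INSTI	raltegravir|isentress
EVG	INSTI	elvitegravir|vitekta
DTG	INSTI	dolutegravir|tivicay
BIC	INSTI	bictegravir
RTV	booster	ritonavir|norvir|r
COBI	booster	cobicistat|tybost|c
MVC	other	maraviroc|selzentry
T20	other	enfuvirtide|fuzeon
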