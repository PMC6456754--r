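id	name	equation	lb	ub	objective
MEOHt	methanol uptake	MEOH_e -> MEOH	0	1000	0
MDH	methanol dehydrogenase	MEOH -> FALD + 0.5 ATP	0	1000	0
FALDH	formaldehyde dehydrogenase	FALD -> FOR + NADH	0	1000	0
FDH	formate dehydrogenase	FOR -> CO2 + NADH	0	1000	0
FORt	formate excretion	FOR -> FOR_e	0	1000	0
CO2t	CO2 exchange	CO2 <=> CO2_e	-1000	1000	0
O2t	O2 uptake	O2_e -> O2	0	1000	0
ETC	electron transport chain	NADH + 0.5 O2 -> 2 ATP	0	1000	0
RUMP	RuMP cycle formaldehyde fixation	6 FALD -> H6P	0	1000	0
EMP	EMP branch (fructose-bisphosphate aldolase, lumped)	H6P -> 2 PYR + 3 ATP + 2 NADH	0	1000	0
EDD	ED branch (6-phosphogluconate dehydratase, lumped)	H6P -> 2 PYR + 1 ATP + 2 NADH	0	1000	0
PPC	PEP/pyruvate carboxylation	PYR + CO2 + ATP -> OAA	0	1000	0
PDH	pyruvate dehydrogenase	PYR -> ACCOA + CO2 + NADH	0	1000	0
MDH2	malate dehydrogenase	OAA + NADH <=> MAL	-1000	1000	0
MCL	malyl-CoA lyase route (malate thiokinase lumped)	MAL + ATP -> ACCOA + GLX	0	1000	0
GLXOX	glyoxylate oxidation (lumped)	GLX -> 2 CO2 + NADH	0	1000	0
CS	citrate synthase	OAA + ACCOA -> CIT	0	1000	0
ICDH	isocitrate dehydrogenase (lumped aconitase)	CIT -> AKG + CO2 + NADH	0	1000	0
AKGDH	alpha-ketoglutarate dehydrogenase	AKG -> SUCCOA + CO2 + NADH	0	1000	0
SCS	succinyl-CoA synthetase	SUCCOA -> SUC + ATP	0	1000	0
SDH	succinate dehydrogenase	SUC -> FUMA + NADH	0	1000	0
FUM	fumarase	FUMA <=> MAL	-1000	1000	0
GLYCS	glycogen synthesis	H6P + ATP -> GLYCOGEN	0	1000	0
GLYCt	glycogen sink	GLYCOGEN -> GLYCOGEN_e	0	1000	0
EPSS	EPS synthesis	H6P + ATP -> EPS	0	1000	0
EPSt	EPS sink	EPS -> EPS_e	0	1000	0
ATPM	ATP maintenance	ATP -> ATP_sink_e	0	1000	0
BIOMASS	biomass (illustrative)	0.2 H6P + 4 PYR + 1.5 OAA + 2.5 ACCOA + 1 AKG + 2.5926 GLYCOGEN + 0.6173 EPS + 54.35 ATP + 8 NADH -> BIOMASS_e	0	1000	1
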