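generic_name	class
albuterol	SABA
levalbuterol	SABA
fluticasone	ICS
budesonide	ICS
beclomethasone	ICS
salmeterol	LABA
formoterol	LABA
montelukast	LTRA
zafirlukast	LTRA
ipratropium	ANTICHOLINERGIC
tiotropium	ANTICHOLINERGIC
fluticasone-salmeterol	ICS_LABA
budesonide-formoterol	ICS_LABA
prednisone	OCS
prednisolone	OCS
methylprednisolone	OCS
dexamethasone	OCS
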