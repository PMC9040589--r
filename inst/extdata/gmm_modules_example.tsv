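module_id	step_index	ortholog_id	name
arginine_deiminase	1	K01478	arginine deiminase pathway
arginine_deiminase	2	K00611	arginine deiminase pathway
arginine_deiminase	3	K00926	arginine deiminase pathway
histidine_degradation	1	K01745	histidine degradation
histidine_degradation	2	K01712	histidine degradation
histidine_degradation	3	K01468	histidine degradation
histidine_degradation	4	K01479	histidine degradation
butyrate_production	1	K00248	butyrate production (terminal steps)
butyrate_production	2	K00634	butyrate production (terminal steps)
butyrate_production	2	K00929	butyrate production (terminal steps)
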