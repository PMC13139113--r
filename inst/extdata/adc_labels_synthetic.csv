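drug_id,pt_code,source_section
brentuximab_vedotin,10029331,warnings_and_precautions
brentuximab_vedotin,10034620,adverse_reactions
brentuximab_vedotin,10034580,adverse_reactions
trastuzumab_emtansine,10029331,adverse_reactions
enfortumab_vedotin,10029331,warnings_and_precautions
enfortumab_vedotin,10034620,adverse_reactions
polatuzumab_vedotin,10029331,warnings_and_precautions
tisotumab_vedotin,10029331,warnings_and_precautions
belantamab_mafodotin,10033775,adverse_reactions
mirvetuximab_soravtansine,10034620,adverse_reactions
sacituzumab_govitecan,10029331,adverse_reactions
trastuzumab_deruxtecan,10029331,adverse_reactions
gemtuzumab_ozogamicin,10029331,adverse_reactions
inotuzumab_ozogamicin,10029331,adverse_reactions
loncastuximab_tesirine,10034620,adverse_reactions
telisotuzumab_vedotin,10029331,adverse_reactions
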