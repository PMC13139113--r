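name,drug_id
ADCETRIS,brentuximab_vedotin
BRENTUXIMAB VEDOTIN,brentuximab_vedotin
KADCYLA,trastuzumab_emtansine
ADO-TRASTUZUMAB EMTANSINE,trastuzumab_emtansine
TRASTUZUMAB EMTANSINE,trastuzumab_emtansine
MYLOTARG,gemtuzumab_ozogamicin
GEMTUZUMAB OZOGAMICIN,gemtuzumab_ozogamicin
BESPONSA,inotuzumab_ozogamicin
INOTUZUMAB OZOGAMICIN,inotuzumab_ozogamicin
POLIVY,polatuzumab_vedotin
POLATUZUMAB VEDOTIN,polatuzumab_vedotin
PADCEV,enfortumab_vedotin
ENFORTUMAB VEDOTIN,enfortumab_vedotin
ENHERTU,trastuzumab_deruxtecan
TRASTUZUMAB DERUXTECAN,trastuzumab_deruxtecan
FAM-TRASTUZUMAB DERUXTECAN-NXKI,trastuzumab_deruxtecan
TRODELVY,sacituzumab_govitecan
SACITUZUMAB GOVITECAN,sacituzumab_govitecan
BLENREP,belantamab_mafodotin
BELANTAMAB MAFODOTIN,belantamab_mafodotin
ZYNLONTA,loncastuximab_tesirine
LONCASTUXIMAB TESIRINE,loncastuximab_tesirine
TIVDAK,tisotumab_vedotin
TISOTUMAB VEDOTIN,tisotumab_vedotin
ELAHERE,mirvetuximab_soravtansine
MIRVETUXIMAB SORAVTANSINE,mirvetuximab_soravtansine
EMRELIS,telisotuzumab_vedotin
TELISOTUZUMAB VEDOTIN,telisotuzumab_vedotin
PACLITAXEL,paclitaxel
TAXOL,paclitaxel
ABRAXANE,nab_paclitaxel
NAB-PACLITAXEL,nab_paclitaxel
DOCETAXEL,docetaxel
TAXOTERE,docetaxel
CABAZITAXEL,cabazitaxel
JEVTANA,cabazitaxel
CISPLATIN,cisplatin
CARBOPLATIN,carboplatin
OXALIPLATIN,oxaliplatin
ELOXATIN,oxaliplatin
VINCRISTINE,vincristine
VINBLASTINE,vinblastine
VINORELBINE,vinorelbine
NAVELBINE,vinorelbine
BORTEZOMIB,bortezomib
VELCADE,bortezomib
THALIDOMIDE,thalidomide
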