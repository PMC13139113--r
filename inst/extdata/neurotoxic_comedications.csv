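drug_id
paclitaxel
docetaxel
nab_paclitaxel
cabazitaxel
cisplatin
carboplatin
oxaliplatin
vincristine
vinblastine
vinorelbine
bortezomib
thalidomide
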