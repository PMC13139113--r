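pt_code,pt_name,provenance
10029331,Neuropathy peripheral,smq
10036105,Polyneuropathy,smq
10034620,Peripheral sensory neuropathy,smq
10034580,Peripheral motor neuropathy,smq
10034623,Peripheral sensorimotor neuropathy,smq
10018767,Guillain-Barre syndrome,smq
10057645,Chronic inflammatory demyelinating polyradiculoneuropathy,smq
10012305,Demyelinating polyneuropathy,smq
10069632,Acute polyneuropathy,curated
10068597,Acute motor-sensory axonal neuropathy,curated
10033987,Paralysis recurrent laryngeal nerve,curated
10033775,Paraesthesia,smq
10020937,Hypoaesthesia,smq
10029223,Neuralgia,smq
10028836,Neuritis,smq
10040026,Sensory loss,smq
10056004,Axonal neuropathy,smq
10061536,Mononeuropathy,smq
10065579,Small fibre neuropathy,curated
10036807,Radiculopathy,curated
10003882,Autonomic neuropathy,curated
10063080,Sensory disturbance,curated
10008990,Burning sensation,mixed
10056672,Polyneuropathy in malignant disease,curated
10028865,Neuromyopathy,curated
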