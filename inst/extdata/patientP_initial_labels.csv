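marker,label
Hsa-miR-155,Norm
Hsa-miR-196a-3p,Norm
Hsa-miR-222-3p,Slight increase
Hsa-let-7a-5p,Slight increase
Micro-196a-2,Norm
Hsa-miR-106a-5p,Slight increase
Has-miR-21-5p,Norm
Hsa-miR-137,Norm
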