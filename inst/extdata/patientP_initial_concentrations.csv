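marker,norm_conc,path_conc
Hsa-miR-155,28294,202238
Hsa-miR-196a-3p,104809,324654
Hsa-miR-222-3p,159928,88908
Hsa-let-7a-5p,13327568,2665531
Micro-196a-2,1665957,333191
Hsa-miR-106a-5p,380633,76126
Has-miR-21-5p,22209402,111047010
Hsa-miR-137,555235050,111047010
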