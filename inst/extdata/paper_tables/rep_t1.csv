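label,exp,calc,scaled,group
nu O4H36,3428,3640.80,3566.16,FG
nu N2H35,3307,3551.09,3478.29,FG
nu C12.16H,2804,2863.56,2804.86,NFG
nu C25O3; beta O4H36,1686,1747.65,1711.82,FG
nu C17O1; beta N2H35; gamma C18H8,1635,1699.94,1665.09,FG
nu C7.18H; N2H,1300,1299.66,1273.02,NFG
gamma N2H35; omega C18H8-9; gamma C7-11H,474,475.74,465.99,NFG
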