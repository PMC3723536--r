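substitution	frequency
N35S	0.10
I116F	singleton
M233V	0.14
M239I	0.90
F257Y	0.50
R349S	0.37
S363G	0.30
T384A	0.20
E403D	0.90
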