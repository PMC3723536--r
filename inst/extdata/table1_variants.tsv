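variant_id	round	substitutions	frequencies	growth_doubling_ser	growth_doubling_lys	efficiency_ser	efficiency_lys
WT	0			ND	63.8	1.55	687
G1-v5	1	A262V;E403D	singleton;0.33	134.5	62.94	9.6	38.4
G2-v15	2	T254A;T287I;R349S;E403G	0.125;singleton;singleton;0.50	77.4	66.3	27.8	141.2
G4-v4	4	D67H;M239I;T254A;K352E;E403D	singleton;0.75;0.42;singleton;0.67	73.4	79.5	60	39.9
G6-v9	6	M239I;F257Y;T384A;A397V	0.52;0.29;0.14;0.35	75	101.4	171	60.9
G7-v12	7	N35S;I116F;M233V;M239I;F257Y;R349S;S363G;T384A;E403D	0.10;singleton;0.14;0.90;0.50;0.37;0.30;0.20;0.90	63.8	101	62.5	35.8
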