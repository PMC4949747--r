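pe,n_acyl,level
32:0,16:0,species
34:1,16:0,species
34:2,16:0,species
36:1,16:0,species
36:2,16:0,species
36:4,16:0,species
38:4,16:0,species
38:6,16:0,species
40:6,16:0,species
32:0,18:0,species
34:1,18:0,species
34:2,18:0,species
36:1,18:0,species
36:2,18:0,species
36:4,18:0,species
38:4,18:0,species
38:6,18:0,species
40:6,18:0,species
32:0,18:1,species
34:1,18:1,species
34:2,18:1,species
36:1,18:1,species
36:2,18:1,species
36:4,18:1,species
38:4,18:1,species
38:6,18:1,species
40:6,18:1,species
32:0,18:2,species
34:1,18:2,species
34:2,18:2,species
36:1,18:2,species
36:2,18:2,species
36:4,18:2,species
38:4,18:2,species
38:6,18:2,species
40:6,18:2,species
32:0,20:4,species
34:1,20:4,species
34:2,20:4,species
36:1,20:4,species
36:2,20:4,species
36:4,20:4,species
38:4,20:4,species
38:6,20:4,species
40:6,20:4,species
32:0,22:6,species
34:1,22:6,species
34:2,22:6,species
36:1,22:6,species
36:2,22:6,species
36:4,22:6,species
38:4,22:6,species
38:6,22:6,species
40:6,22:6,species
34:1,17:0,species
34:2,17:0,species
36:1,17:0,species
36:2,17:0,species
38:4,17:0,species
18:1/18:1,19:0,molecular
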