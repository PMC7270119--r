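gene_id,direction,fc_h1_p1,fc_h1_p2,fc_h2_p1,fc_h2_p2,label_h1,label_h2
c47423g1i1,up,2.75,2.69,2.21,2.14,overdominance,overdominance
c54944g1i1,up,2.15,1.60,2.69,2.22,dominance,overdominance
c60389g1i1,up,1.23,1.35,2.75,3.69,additive,overdominance
c60389g1i2,up,1.18,1.14,2.35,3.02,additive,overdominance
c49702g1i1,up,2.96,2.77,4.85,3.18,overdominance,overdominance
c52443g1i1,up,2.27,1.75,7.99,7.26,dominance,overdominance
c57602g1i1,up,2.76,3.22,1.16,1.24,overdominance,additive
c59275g1i2,up,2.20,2.16,5.80,4.39,overdominance,overdominance
c62533g1i1,up,2.46,2.13,1.25,1.27,overdominance,additive
c63435g1i2,up,1.29,1.19,3.97,3.22,additive,overdominance
c64671g4i2,up,1.63,1.39,2.25,2.38,additive,overdominance
c60887g1i2,up,1.87,2.21,2.47,2.79,dominance,overdominance
c52384g1i2,down,-1.97,-2.96,-2.38,-2.18,dominance,overdominance
c58513g1i1,down,-2.63,-4.58,-2.84,-3.66,overdominance,overdominance
c47447g1i1,down,-4.33,-3.18,-1.92,-2.04,overdominance,dominance
c63663g3i2,down,-2.84,-2.49,-2.06,-2.11,overdominance,overdominance
c47368g1i1,down,-3.74,-2.04,-2.32,-2.88,overdominance,overdominance
c59731g1i1,down,-2.76,-4.20,-3.94,-2.22,overdominance,overdominance
c47856g3i1,down,-1.78,-1.66,-2.37,-2.39,additive,overdominance
c37944g1i1,down,-2.41,-5.84,-3.36,-2.88,overdominance,overdominance
c55548g2i1,down,-1.38,-1.45,-2.47,-2.08,additive,overdominance
c56718g1i1,down,-1.74,-1.59,-2.60,-2.71,additive,overdominance
c57368g1i1,down,-1.34,-1.19,-2.26,-2.03,additive,overdominance
c60709g3i1,down,-3.59,-4.70,-1.19,-1.13,overdominance,additive
c80430g1i1,down,-2.91,-4.30,-1.27,-1.27,overdominance,additive
c96948g1i1,down,-2.95,-6.14,-2.62,-1.99,overdominance,dominance
c13258g1i1,down,-2.33,-2.74,-3.25,-2.23,overdominance,overdominance
c22243g1i1,down,-2.83,-2.58,-1.59,-1.18,overdominance,additive
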