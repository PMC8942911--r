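experiment,condition,item_class,p1,p2,p3,p4,mean_rating
e1,colour,target,0.089,0.165,0.199,0.547,3.204
e1,colour,category_lure,0.568,0.309,0.074,0.049,1.605
e1,colour,colour_lure,0.436,0.370,0.123,0.070,1.827
e1,colour,critical_lure,0.362,0.391,0.140,0.107,1.992
e1,category,target,0.044,0.105,0.181,0.669,3.476
e1,category,category_lure,0.547,0.316,0.103,0.034,1.624
e1,category,colour_lure,0.859,0.098,0.021,0.021,1.205
e1,category,critical_lure,0.393,0.325,0.162,0.120,2.008
e2,colour,target,0.059,0.105,0.214,0.622,3.400
e2,colour,category_lure,0.857,0.062,0.052,0.029,1.252
e2,colour,colour_lure,0.738,0.152,0.081,0.029,1.400
e2,colour,critical_lure,0.270,0.251,0.289,0.190,2.400
e2,category,target,0.063,0.105,0.148,0.684,3.452
e2,category,category_lure,0.602,0.222,0.097,0.079,1.653
e2,category,colour_lure,0.755,0.120,0.069,0.056,1.426
e2,category,critical_lure,0.321,0.278,0.219,0.182,2.262
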