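name,svm,mlr,bn,dock,is_control
Lathyranoic acid A,4.81,5.12,5.45,86.20,FALSE
Daphnetoxin,5.09,8.89,7.46,84.88,FALSE
Aurantiamide,4.89,6.42,5.43,83.89,FALSE
(6aR11aR)-910-Dimethoxypterocarpan-3-O-beta-D-glucoside,5.00,8.33,5.56,83.50,FALSE
Picrasidine M,5.10,7.51,5.65,69.60,FALSE
12-O-Acetylphorbol-13-tigliate,4.91,7.40,6.15,68.88,FALSE
20-O-(2'E4'E-Decadienoyl)ingenol,4.91,6.87,6.35,68.52,FALSE
Howiinol A II,5.24,6.87,5.40,68.11,FALSE
Moellendorffiline,5.15,6.64,5.98,63.24,FALSE
Lythrancine II,5.03,8.92,6.74,62.03,FALSE
Tacrolimus,5.11,6.25,5.33,58.10,TRUE
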