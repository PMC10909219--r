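algorithm,accuracy_before,accuracy_after,recall_before,recall_after
ALS_User_CF,0.71,0.74,0.63,0.67
FunkSVD,0.61,0.66,0.51,0.53
SVD,0.60,0.63,0.49,0.51
CF,0.51,0.53,0.41,0.42
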