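quantity,printed,recomputed,note
"model 1 consistency, corner (Empowerment=0, Design=0, Lay-led=1)",0.666,0.800,"Sum of member outcomes (1 + 1 + 1 + 0.333 + 0.666) / 5; the printed 0.666 would require Long = 0 and Shaw = 0.333."
"model 1 consistency, corner (Empowerment=0, Design=0, Lay-led=0)",0.666,0.777,"(0.666 + 1 + 0.666) / 3 from the data-table outcomes of Grummer-Strawn, Pugh 2001 and Pugh 2002."
"model 1 consistency, corner (Empowerment=1, Design=1, Lay-led=0)",0.333,0.666,"Single member Chapman has data-table outcome 0.666."
"model 3 consistency, corner (Intensity=0, Quality=1)",0.750,0.666,"Single member Chapman has data-table outcome 0.666; 0.750 is not a calibration level and is unreachable from a one-study row."
"model 3 consistency, corner (Intensity=0, Quality=0)",0.389,0.500,"Sum of min(config, outcome) 2.998 over configuration membership 6."
"model 3 solution coverage",0.714,0.640,"Sum of min(solution, outcome) 5.332 over total outcome membership 8.330."
"model 3 solution consistency",0.833,0.889,"Sum of min(solution, outcome) 5.332 over total solution membership 6."
"model 3 raw coverage of Intensity",0.667,0.560,"Sum of min(Intensity, outcome) 4.666 over 8.330; the solution table labels this column 'unique coverage', but the components overlap on four studies so true unique coverages are far smaller."
"model 3 raw coverage of Quality",0.619,0.560,"Sum of min(Quality, outcome) 4.665 over 8.330."
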