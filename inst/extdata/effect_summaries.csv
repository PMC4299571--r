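intervention,population,total_cost,or_baby,or_baby_lo,or_baby_hi,or_mother,or_mother_lo,or_mother_hi,babies_saved,babies_saved_lo,babies_saved_hi,mothers_saved,mothers_saved_lo,mothers_saved_hi,dalys_averted,dalys_averted_lo,dalys_averted_hi
CI,108000,5348791,0.873,0.774,0.982,0.957,0.494,1.657,772,109,1384,18,-270,210,67361,8808,121508
FI,108000,5592212,0.954,0.846,1.070,1.228,0.652,2.135,291,-439,974,-97,-480,148,19901,-44769,80586
FICI,54000,5470501,0.841,0.707,0.992,1.287,0.488,2.839,475,23,880,-62,-397,112,37590,-4642,74618
FICI2,108000,10941002,0.841,0.707,0.992,1.287,0.488,2.839,951,46,1760,-124,-793,223,75180,-9284,149236
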