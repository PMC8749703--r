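parameter,placement,direction,mean_ss,sd_ss,mean_hi,sd_hi,p_printed
n_cycles,shank_leading,,5.86,1.56,3.5,0.94,0.001
turn_duration,shank_leading,,7.67,3.17,3.72,1.74,0.004
stance_pct,shank_leading,,53.28,13.59,38.96,12.57,0.013
angular_velocity,sternum,flexext,0.89,0.41,1.43,0.35,0.001
angular_velocity,sacrum,flexext,0.97,0.44,1.42,0.34,0.004
angular_velocity,shank_leading,flexext,1.71,0.37,2.24,0.37,0.004
range_of_motion,sternum,lateral,11.51,5.03,7.3,3.48,0.021
range_of_motion,sacrum,lateral,8.88,2.36,7.31,1.56,0.033
range_of_motion,sternum,flexext,8.69,2.9,5.24,1.84,0.004
range_of_motion,sacrum,flexext,7.56,2.73,5.07,1.28,0.014
range_of_motion,shank_leading,flexext,18.82,7.64,16.22,5.73,0.324
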