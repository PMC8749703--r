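parameter,placement,direction,group,k2_p1,k2_p2,cmp2_2v1,k4_p1,k4_p2,k4_p3,k4_p4,cmp4_2v1,cmp4_3v2,cmp4_4v3
angular_velocity,sternum,flexext,SS,0.77,0.67,-14,0.71,0.84,0.84,0.59,17,0,-35
angular_velocity,sternum,flexext,HI,1.85,1.08,-53,1.76,1.94,1.82,0.84,10,-6,-74
angular_velocity,sacrum,flexext,SS,0.82,0.72,-13,0.75,0.91,0.9,0.63,19,-1,-35
angular_velocity,sacrum,flexext,HI,1.85,1.08,-53,1.77,1.94,1.84,0.83,9,-5,-76
angular_velocity,shank_leading,flexext,SS,0.8,0.7,-13,0.7,0.85,0.83,0.66,19,-2,-23
angular_velocity,shank_leading,flexext,HI,1.41,1.03,-31,0.38,1.8,1.42,0.82,130,-24,-54
angular_velocity,shank_trailing,flexext,SS,0.86,0.75,-14,0.83,1.08,1.01,0.64,26,-7,-45
angular_velocity,shank_trailing,flexext,HI,2.26,1.13,-67,3.4,2.01,2.68,0.86,-51,29,-103
angular_velocity,sternum,rotation,SS,0.23,0.18,-24,0.21,0.26,0.26,0.15,21,0,-54
angular_velocity,sternum,rotation,HI,0.4,0.21,-62,0.37,0.42,0.39,0.15,13,-7,-89
angular_velocity,sacrum,rotation,SS,0.15,0.14,-7,0.14,0.17,0.17,0.13,19,0,-27
angular_velocity,sacrum,rotation,HI,0.39,0.24,-48,0.36,0.4,0.4,0.19,11,0,-71
angular_velocity,shank_leading,rotation,SS,0.06,0.05,-18,0.05,0.06,0.05,0.06,18,-18,18
angular_velocity,shank_leading,rotation,HI,0.23,0.17,-30,0.13,0.3,0.21,0.16,79,-35,-27
angular_velocity,shank_trailing,rotation,SS,0.06,0.04,-40,0.08,0.12,0.05,0.07,40,-82,33
angular_velocity,shank_trailing,rotation,HI,0.34,0.1,-109,0.48,0.28,0.44,0.11,-53,44,-120
angular_velocity,sternum,lateral,SS,0.13,0.09,-36,0.13,0.13,0.13,0.09,0,0,-36
angular_velocity,sternum,lateral,HI,0.15,0.07,-73,0.14,0.16,0.13,0.06,13,-21,-74
angular_velocity,sacrum,lateral,SS,0.05,0.04,-22,0.04,0.07,0.06,0.04,55,-15,-40
angular_velocity,sacrum,lateral,HI,0.14,0.09,-43,0.17,0.13,0.14,0.08,-27,7,-55
range_of_motion,sternum,flexext,SS,7.07,7.77,9,6.03,5.97,5.55,6.77,-1,-7,20
range_of_motion,sternum,flexext,HI,4.41,4.42,0,1.84,3.6,3.15,3.65,65,-13,15
range_of_motion,sacrum,flexext,SS,6.18,6.88,11,5.28,5.14,5.48,6.13,-3,6,11
range_of_motion,sacrum,flexext,HI,3.41,4.13,19,1.85,3.08,2.92,3.65,50,-5,22
range_of_motion,shank_leading,flexext,SS,17.11,17.84,4,13.8,14.73,15.67,15.78,7,6,1
range_of_motion,shank_leading,flexext,HI,10.64,14.98,34,3.25,9.85,9.62,12.83,101,-2,29
range_of_motion,shank_trailing,flexext,SS,19.11,20.19,5,18.04,16.77,17.68,17.76,-7,5,0
range_of_motion,shank_trailing,flexext,HI,23.1,23.36,1,16.6,20.23,19.24,19.33,20,-5,0
range_of_motion,sacrum,lateral,SS,7.54,7.65,1,6.02,6.04,5.63,7.15,0,-7,24
range_of_motion,sacrum,lateral,HI,5.47,6.71,20,3.03,4.46,3.62,5.81,38,-21,46
range_of_motion,sternum,lateral,SS,9.46,12.82,30,7.65,7.47,6.72,12.33,-2,-11,59
range_of_motion,sternum,lateral,HI,4.65,6.89,39,2.37,4.09,3.58,5.88,53,-13,49
ratio_angular_velocity,leading_trailing,flexext,SS,0.95,0.94,-1,0.85,1.03,0.8,1.05,19,-25,27
ratio_angular_velocity,leading_trailing,flexext,HI,0.74,0.96,26,0.17,1.22,0.95,0.95,151,-25,0
ratio_angular_velocity,leading_trailing,rotation,SS,5.32,18.52,111,4.72,2.21,4.16,1.58,-72,61,-90
ratio_angular_velocity,leading_trailing,rotation,HI,1.05,2.01,63,0.32,1.92,10.71,12.25,143,139,13
ratio_range_of_motion,leading_trailing,flexext,SS,1.11,1.07,-4,1.04,1.15,1.24,1.18,10,8,-5
ratio_range_of_motion,leading_trailing,flexext,HI,0.87,0.93,7,0.34,1.08,1.23,0.87,104,13,-34
rel_range_of_motion,sternum_sacrum,rotation,SS,21.94,21.27,-3,46.09,25.24,33.81,28.25,-58,29,-18
rel_range_of_motion,sternum_sacrum,rotation,HI,24.28,9.9,-84,39.3,21.85,6.45,13.97,-57,-109,74
rel_range_of_motion,sternum_sacrum,lateral,SS,14.64,15.84,8,14.68,14.74,15.83,15.97,0,7,1
rel_range_of_motion,sternum_sacrum,lateral,HI,12.26,11.98,-2,12.4,12.34,12.81,11.83,0,4,-8
rel_range_of_motion,sternum_sacrum,flexext,SS,9.05,8.77,-3,9.04,9.02,8.69,8.81,0,-4,1
rel_range_of_motion,sternum_sacrum,flexext,HI,5.75,5.2,-10,5.88,5.82,5.05,5.28,-1,-14,4
rel_angular_velocity,sternum_sacrum,rotation,SS,0.19,0.18,-5,0.18,0.21,0.24,0.16,15,13,-40
rel_angular_velocity,sternum_sacrum,rotation,HI,0.44,0.26,-51,0.41,0.45,0.44,0.2,9,-2,-75
rel_angular_velocity,sternum_sacrum,lateral,SS,0.14,0.1,-33,0.13,0.17,0.15,0.09,27,-13,-50
rel_angular_velocity,sternum_sacrum,lateral,HI,0.17,0.11,-43,0.18,0.17,0.19,0.09,-6,11,-71
rel_angular_velocity,sternum_sacrum,flexext,SS,0.07,0.06,-15,0.05,0.09,0.08,0.05,57,-12,-46
rel_angular_velocity,sternum_sacrum,flexext,HI,0.06,0.03,-67,0.06,0.09,0.05,0.03,40,-57,-50
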