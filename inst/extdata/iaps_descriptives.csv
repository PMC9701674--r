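measure,group,m,sd,mdn,min,max,n
gaze_gesture_delay,ASD,264.05,103.13,248.05,123.45,520.70,24
gaze_gesture_delay,TD,206.02,59.45,202.85,108.91,333.25,24
sd_of_delays,ASD,95.19,44.64,81.15,42.05,251.6,24
sd_of_delays,TD,81.02,46.69,72.46,36.09,259.33,24
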