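"dimension","level","decrement"
"mobility",2,0.07
"self_care",2,0.09
"usual_activities",2,0.04
"pain_discomfort",2,0.08
"anxiety_depression",2,0.06
"mobility",3,0.198
"self_care",3,0.254
"usual_activities",3,0.104
"pain_discomfort",3,0.268
"anxiety_depression",3,0.202
"any_level_3",NA,0.568
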