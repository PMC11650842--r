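"dimension","level","decrement"
"mobility",2,0.1
"self_care",2,0.1
"usual_activities",2,0.1
"pain_discomfort",2,0.1
"anxiety_depression",2,0.1
"mobility",3,0.2
"self_care",3,0.2
"usual_activities",3,0.2
"pain_discomfort",3,0.2
"anxiety_depression",3,0.2
"any_level_3",NA,0
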