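"id","parent_id","length_cm","radius_cm","wall_ratio"
"s1","",1,0.13,0.1
"s2","s1",0.70863,0.118105,0.1
"s3","s1",0.52377,0.087295,0.1
"s4","s2",0.643790355,0.1072983925,0.1
"s5","s2",0.475845045,0.0793075075,0.1
"s6","s3",0.351711555,0.0586185925,0.1
"s7","s3",0.475845045,0.0793075075,0.1
"s8","s4",0.4323052233825,0.07205087056375,0.1
"s9","s4",0.5848835375175,0.09748058958625,0.1
"s10","s5",0.4323052233825,0.07205087056375,0.1
"s11","s5",0.3195299477175,0.05325499128625,0.1
"s12","s6",0.2361743091825,0.03936238486375,0.1
"s13","s6",0.3195299477175,0.05325499128625,0.1
"s14","s7",0.3195299477175,0.05325499128625,0.1
"s15","s7",0.4323052233825,0.07205087056375,0.1
"s16","s8",0.290292957501349,0.0483821595835581,0.1
"s17","s8",0.392749295443001,0.0654582159071669,0.1
"s18","s9",0.392749295443001,0.0654582159071669,0.1
"s19","s9",0.531366693834649,0.0885611156391081,0.1
"s20","s10",0.392749295443001,0.0654582159071669,0.1
"s21","s10",0.290292957501349,0.0483821595835581,0.1
"s22","s11",0.290292957501349,0.0483821595835581,0.1
"s23","s11",0.214564359892301,0.0357607266487169,0.1
"s24","s12",0.214564359892301,0.0357607266487169,0.1
"s25","s12",0.158591048616049,0.0264318414360081,0.1
"s26","s13",0.214564359892301,0.0357607266487169,0.1
"s27","s13",0.290292957501349,0.0483821595835581,0.1
"s28","s14",0.290292957501349,0.0483821595835581,0.1
"s29","s14",0.214564359892301,0.0357607266487169,0.1
"s30","s15",0.290292957501349,0.0483821595835581,0.1
"s31","s15",0.392749295443001,0.0654582159071669,0.1
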