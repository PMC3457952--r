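"sex","month","age_class","proportion"
"male","May","class1",0.17
"male","May","class2",0.4004
"male","May","class3",0.2519
"male","May","class4",0.1777
"male","Jun","class1",0.4609
"male","Jun","class2",0.1676
"male","Jun","class3",0.2745
"male","Jun","class4",0.097
"male","Jul","class1",0.5122
"male","Jul","class2",0.1365
"male","Jul","class3",0.0938
"male","Jul","class4",0.2575
"male","Aug","class1",0.424
"male","Aug","class2",0.4464
"male","Aug","class3",0.0288
"male","Aug","class4",0.1008
"male","Sep","class1",0.1022
"male","Sep","class2",0.441
"male","Sep","class3",0.2229
"male","Sep","class4",0.2339
"female","May","class1",0.177917791779178
"female","May","class2",0.222522252225223
"female","May","class3",0.345034503450345
"female","May","class4",0.254525452545255
"female","Jun","class1",0.1465
"female","Jun","class2",0.1238
"female","Jun","class3",0.2909
"female","Jun","class4",0.4388
"female","Jul","class1",0.128612861286129
"female","Jul","class2",0.554755475547555
"female","Jul","class3",0.107210721072107
"female","Jul","class4",0.209420942094209
"female","Aug","class1",0.1181
"female","Aug","class2",0.1454
"female","Aug","class3",0.5892
"female","Aug","class4",0.1473
"female","Sep","class1",0.173482651734827
"female","Sep","class2",0.382061793820618
"female","Sep","class3",0.287871212878712
"female","Sep","class4",0.156584341565843
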