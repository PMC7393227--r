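# synthetic PAM assay: control vs lincomycin-treated aliquots
time_h,value,inhibitor,replicate
0,0.55649823455444,FALSE,1
0.3,0.49146657414666933,FALSE,1
1,0.3953061037816069,FALSE,1
2,0.30835633151896324,FALSE,1
3,0.2731651484088632,FALSE,1
4.5,0.17630790431591278,FALSE,1
6,0.12833061624449812,FALSE,1
0,0.5288994974629864,TRUE,1
0.3,0.4868411294514347,TRUE,1
1,0.31883298658132864,TRUE,1
2,0.17892992228716117,TRUE,1
3,0.1048890951365958,TRUE,1
4.5,0.029956827431664,TRUE,1
6,0.020427072352326426,TRUE,1
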