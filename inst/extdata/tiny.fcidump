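 &FCI NORB=3,NELEC=2,MS2=0,
  ORBSYM=1,1,1,
  ISYM=1,
 &END
1.46063680672950252e-01 1 1 1 1
-1.23233740831456620e-02 2 1 1 1
5.84070901667341144e-02 2 1 2 1
-4.16401259970017052e-03 2 2 1 1
9.78700435323065082e-02 2 2 2 1
1.77792543407205378e-01 2 2 2 2
-3.16445906918042738e-02 3 1 1 1
1.95416121019215162e-02 3 1 2 1
2.26171226165770463e-02 3 1 2 2
1.65198581893871987e-02 3 1 3 1
-5.51153217181516442e-02 3 2 1 1
1.66474995416928083e-02 3 2 2 1
3.50716451459692491e-02 3 2 2 2
7.40400068051499504e-03 3 2 3 1
4.49916821304920042e-02 3 2 3 2
6.04310725938056043e-02 3 3 1 1
-4.75881900687598058e-02 3 3 2 1
-6.72409555416211002e-02 3 3 2 2
-3.52283520707568423e-02 3 3 3 1
-4.14512447268149953e-02 3 3 3 2
1.73932059091562896e-01 3 3 3 3
-1.64606368067295028e+00 1 1 0 0
1.23233740831456620e-02 2 1 0 0
8.21864965370002754e-01 2 2 0 0
3.16445906918042738e-02 3 1 0 0
1.29772255538224801e-01 3 2 0 0
6.97715204151529322e-01 3 3 0 0
-1.50000000000000000e+00 1 0 0 0
7.55129850003868341e-01 2 0 0 0
8.02057491149753332e-01 3 0 0 0
0.00000000000000000e+00 0 0 0 0
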