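 &FCI NORB=5,NELEC=4,MS2=0,
  ORBSYM=1,1,1,1,1,
  ISYM=1,
 &END
2.58896955916008253e-01 1 1 1 1
-3.61642435197662218e-02 2 1 1 1
9.06666487273011384e-02 2 1 2 1
-1.15489810543432436e-01 2 2 1 1
-1.89682267122874941e-02 2 2 2 1
1.00701165508069124e-01 2 2 2 2
-1.59330468051221870e-02 3 1 1 1
-3.48642421799301161e-02 3 1 2 1
1.35202073836092410e-02 3 1 2 2
4.40322188401601131e-02 3 1 3 1
7.70896320818898612e-02 3 2 1 1
-2.92478590371098440e-02 3 2 2 1
-2.87973384631878826e-02 3 2 2 2
3.39597867123703559e-02 3 2 3 1
1.46089232625400356e-01 3 2 3 2
8.35536278393931436e-02 3 3 1 1
-6.93745293697866500e-02 3 3 2 1
-1.40186741152430513e-02 3 3 2 2
5.95182914150362979e-02 3 3 3 1
1.06514490837402220e-01 3 3 3 2
2.14238837470245275e-01 3 3 3 3
4.38355767760304008e-02 4 1 1 1
-2.51731717136466637e-02 4 1 2 1
-1.08272771096386399e-02 4 1 2 2
2.46488044582325767e-02 4 1 3 1
6.36446168554186675e-02 4 1 3 2
5.26074615498132586e-02 4 1 3 3
4.16258071290325146e-02 4 1 4 1
3.28615455853549857e-02 4 2 1 1
-1.59556826467635825e-02 4 2 2 1
-4.69366747057686079e-03 4 2 2 2
-2.61487916174091631e-03 4 2 3 1
-2.73245620805940490e-02 4 2 3 2
2.59138202006247258e-02 4 2 3 3
-1.61114021937761899e-02 4 2 4 1
3.81301280572876045e-02 4 2 4 2
-2.20666585339893070e-02 4 3 1 1
3.44828520633769509e-02 4 3 2 1
-2.57870620245292774e-02 4 3 2 2
-9.92582221730770129e-04 4 3 3 1
1.35530219881031117e-03 4 3 3 2
-1.47848616392269212e-02 4 3 3 3
-6.17647517472110809e-03 4 3 4 1
-1.25887562390679161e-02 4 3 4 2
3.02029086089502033e-02 4 3 4 3
1.62286573645013012e-02 4 4 1 1
-5.83228686163243595e-02 4 4 2 1
7.11269561156901986e-02 4 4 2 2
-1.16677908470430164e-02 4 4 3 1
1.78003274348789708e-02 4 4 3 2
6.93924899152997647e-03 4 4 3 3
2.44559188735194721e-02 4 4 4 1
-1.11275821961959245e-02 4 4 4 2
-6.20819597893420144e-02 4 4 4 3
1.86057785135635118e-01 4 4 4 4
-2.83023287605451250e-02 5 1 1 1
-5.24021104021891223e-03 5 1 2 1
-1.76163175256114357e-02 5 1 2 2
3.91152178363335292e-03 5 1 3 1
-2.01145503331779767e-02 5 1 3 2
-2.99513237601212838e-02 5 1 3 3
-7.61384702702939779e-03 5 1 4 1
-1.18074805299215324e-02 5 1 4 2
1.80614143118426711e-02 5 1 4 3
-3.34096764865924878e-02 5 1 4 4
4.49194980900265439e-02 5 1 5 1
9.14589601525158113e-02 5 2 1 1
4.29373117525980348e-03 5 2 2 1
-3.64225528978986621e-02 5 2 2 2
7.40623517332094326e-03 5 2 3 1
4.59112187426343604e-02 5 2 3 2
2.30043148780369779e-02 5 2 3 3
2.95536131974336452e-02 5 2 4 1
4.59525715314571936e-03 5 2 4 2
-4.98199452601690452e-03 5 2 4 3
-1.24759537894472000e-02 5 2 4 4
-3.04404664362276055e-02 5 2 5 1
7.51990120450476557e-02 5 2 5 2
1.18845458086820083e-02 5 3 1 1
2.84744511984005404e-02 5 3 2 1
-3.93657476402206954e-02 5 3 2 2
-6.81226561031142343e-03 5 3 3 1
1.22279203140665052e-02 5 3 3 2
-5.56752742346919294e-03 5 3 3 3
5.08437424363312324e-03 5 3 4 1
-1.74714469676712572e-02 5 3 4 2
2.51356357494514904e-02 5 3 4 3
-3.73121932136159448e-02 5 3 4 4
1.83532498526143527e-02 5 3 5 1
-1.47650300044350384e-03 5 3 5 2
3.30720750265320051e-02 5 3 5 3
-1.31668568067617925e-01 5 4 1 1
3.53336716655298921e-02 5 4 2 1
8.40783485971888928e-02 5 4 2 2
8.90438970673298157e-03 5 4 3 1
2.22541090083130206e-03 5 4 3 2
-3.10727216225880759e-02 5 4 3 3
1.97968151309835813e-03 5 4 4 1
-3.75557625939725859e-02 5 4 4 2
1.29466486391580852e-03 5 4 4 3
4.08733460084581071e-02 5 4 4 4
-2.26995689592101521e-02 5 4 5 1
-1.80033468227726937e-02 5 4 5 2
-1.06321496110718984e-02 5 4 5 3
1.25579990392747115e-01 5 4 5 4
3.45922288844043788e-02 5 5 1 1
8.14849628664068154e-03 5 5 2 1
-3.98862749785257598e-02 5 5 2 2
-2.22005862460020985e-02 5 5 3 1
-1.65392435100267417e-02 5 5 3 2
-6.46163024477634240e-02 5 5 3 3
-1.56104784417204559e-02 5 5 4 1
2.41026947007952266e-03 5 5 4 2
9.37254645761381733e-03 5 5 4 3
-3.27382611829922301e-02 5 5 4 4
2.22973733979990874e-02 5 5 5 1
8.08502282329727137e-03 5 5 5 2
7.20378301656315195e-03 5 5 5 3
-4.77312370098380845e-02 5 5 5 4
5.67379845829119253e-02 5 5 5 5
-1.43976899561494909e+00 1 1 0 0
5.51324702320537124e-02 2 1 0 0
-1.27905489569390318e+00 2 2 0 0
-4.03552269992061355e-02 3 1 0 0
-1.60246167880521956e-01 3 2 0 0
7.12445503949274694e-02 3 3 0 0
-3.81367052035166965e-02 4 1 0 0
-8.62025954137797812e-02 4 2 0 0
9.30316834946756932e-02 4 3 0 0
2.67914075229377990e-01 4 4 0 0
6.78286949870278155e-02 5 1 0 0
-1.51735578447351860e-01 5 2 0 0
1.04785144189345092e-01 5 3 0 0
9.21618490669743884e-02 5 4 0 0
5.14395242638402639e-01 5 5 0 0
-1.50251830951310694e+00 1 0 0 0
-1.50000000000000000e+00 2 0 0 0
2.01930063776671886e-02 3 0 0 0
3.62869367003440857e-01 4 0 0 0
3.83688640315085649e-01 5 0 0 0
0.00000000000000000e+00 0 0 0 0
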