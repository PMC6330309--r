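antigen,totalScreened,antigenSpecific,totalFamilies,specificFamilies,lambdaPercent
Human BCMA,309,54,171,28,4.9
Human and cynomolgus CD38,173,42,96,37,1.2
Human PSMA,265,41,97,15,0.8
Human and cynomolgus PD-1,252,39,85,20,2.4
Human and cynomolgus BCMA,334,120,111,28,9
Mouse CD38,218,91,89,37,7.8
Human and cynomolgus CD22,277,55,123,22,2.5
Human PD-L1,329,61,189,37,5.8
HIV-1 gp120 envelope protein,174,27,100,14,NA
Human PSCA,269,30,70,10,8.9
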