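wavelength_nm,lens_density,macular_density
390,2.08510112870786,0.000248929002032322
395,1.91838564740497,0.000675658947679698
400,1.765,0.00170316684396495
405,1.57939139417736,0.00398716751763639
410,1.41330151614817,0.00866860867739397
415,1.26467776316274,0.0175029777624044
420,1.13168338557887,0.032821022801878
425,1.01267478760157,0.0571570634179598
430,0.906181215092525,0.0924411483274764
435,0.81088657942341,0.138847601763648
440,0.725613192745186,0.193681910763783
445,0.649307213667596,0.250909650909762
450,0.581025623480953,0.301872324189982
455,0.519924571967339,0.337292634762247
460,0.465248948774258,0.35
465,0.416323051469761,0.337292634762247
470,0.372542234951274,0.301872324189982
475,0.333365439008297,0.250909650909762
480,0.298308501691707,0.193681910763783
485,0.266938175853725,0.138847601763648
490,0.238866774912621,0.0924411483274764
495,0.213747381672462,0.0571570634179598
500,0.191269560986646,0.032821022801878
505,0.171155523280675,0.0175029777624044
510,0.153156691521485,0.00866860867739397
515,0.137050629206635,0.00398716751763639
520,0.122638291408245,0.00170316684396495
525,0.109741564899035,0.000675658947679698
530,0.0982010669603926,0.000248929002032322
535,0.0878741756692799,8.51728325588089e-05
540,0.0786332673215243,2.70647681057697e-05
545,0.0703641392088745,7.98702708432344e-06
550,0.0629645982579005,2.18898926126256e-06
555,0.0563431980885909,5.57159746298128e-07
560,0.0504181088847314,1.31702330506706e-07
565,0.0451161061094856,2.89124446978721e-08
570,0.0403716655683367,5.89459263676844e-09
575,0.0361261536358286,1.11609305711236e-09
580,0.0323271026386158,1.96256768158734e-10
585,0.028927562439727,3.20498872681502e-11
590,0.0258855202106703,4.86078035273741e-12
595,0.0231633812207008,0
600,0.0207275042266427,0
605,0.0185477857214359,0
610,0.016597287903389,0
615,0.0148519057684401,0
620,0.0132900692112223,0
625,0.0118924764533858,0
630,0.0106418555047788,0
635,0.00952275070953348,0
640,0.00852133173911249,0
645,0.00762522267177603,0
650,0.00682334904616951,0
655,0.0061058009988603,0
660,0.00546371079442465,0
665,0.00488914323455425,0
670,0.00437499759181612,0
675,0.00391491985612525,0
680,0.00350322420943813,0
685,0.00313482275822118,0
690,0.00280516265530078,0
695,0.00251016983402253,0
700,0.00224619865936476,0
705,0.00200998687377532,0
710,0.00179861528093495,0
715,0.00160947166920372,0
720,0.00144021852890234,0
725,0.00128876416446637,0
730,0.00115323684446593,0
735,0.00103196167002705,0
740,0.000923439875785621,0
745,0.000826330307567151,0
750,0.000739432847886398,0
755,0.000661673584432768,0
760,0.000592091538247933,0
765,0.00052982678757735,0
770,0.000474109840625668,0
775,0.000424252125880442,0
780,0.000379637482479899,0
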