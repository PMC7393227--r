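# synthetic phycobilisome emission spectrum, 530 nm excitation
wavelength_nm,intensity
545,2.3503747188576007e-5
546,0.012203987998971984
547,0.03895608540721134
548,0.0379419291766647
549,0.0895380008773885
550,0.08897569904025764
551,0.12976165613140045
552,0.14982467203271072
553,0.22324075671746002
554,0.2658388296179922
555,0.35981830354466454
556,0.4681365942061956
557,0.5681462101178043
558,0.6737025653689542
559,0.8169685117663954
560,0.9542040000550566
561,1.1082288379803906
562,1.2772601082083364
563,1.424271767523495
564,1.5947683697187331
565,1.720242104461563
566,1.8494075821359595
567,1.9420117254739895
568,2.037160265698616
569,2.0719544513042782
570,2.1104368748643303
571,2.0727760097208803
572,2.0483429405600764
573,1.945364045899539
574,1.8403760100577515
575,1.7181764270959965
576,1.5915926151235087
577,1.4186295683235595
578,1.2641826823552238
579,1.1067441540144158
580,0.9637083086900504
581,0.793375495022425
582,0.6845676817510344
583,0.5559490514597984
584,0.4297839782367499
585,0.361175023821594
586,0.30890923361486716
587,0.20378108625607
588,0.15593597968872466
589,0.11858048256549808
590,0.08027810148683802
591,0.06845681717687423
592,0.041081442371659206
593,0.020086611786069967
594,0.012780284569330832
595,0.00996617836150877
596,0.00806336604572324
597,0.003757208137381342
598,0.012722404875664749
599,0
600,0
601,0.007115605412043015
602,0
603,0
604,0
605,0.015931552211460216
606,0.003907942410119049
607,0
608,0
609,0.01377740501584537
610,0
611,0.011867316752968099
612,0
613,0
614,0
615,0
616,0
617,0
618,0
619,0.014244021058925836
620,0
621,0
622,0
623,0
624,0.007480715658950626
625,0
626,0.027131459470332114
627,0.001485744648250524
628,0.018558256844356597
629,0.011175114291170813
630,0.007034506962586149
631,0
632,0
633,0.02328432926897206
634,0.040134396308175134
635,0.06119112254778526
636,0.10997601937170558
637,0.1298634330574658
638,0.18816313172664412
639,0.24564741929275336
640,0.3180553502446296
641,0.4354778055429037
642,0.517505975403436
643,0.6545484390449116
644,0.8037202070915899
645,0.9237324095582298
646,1.040726670842173
647,1.152125295815297
648,1.2261310594794057
649,1.283398997338615
650,1.3011151814357487
651,1.2810118213268176
652,1.245334527714552
653,1.1471008585846811
654,1.0423655377195333
655,0.9150160289587932
656,0.7718951966381195
657,0.649041956183839
658,0.5477209756566858
659,0.41201077155742044
660,0.33150010415509096
661,0.24385639157494277
662,0.17136457811935263
663,0.12732550823936387
664,0.09070936034946443
665,0.06065785541212445
666,0.054072841170817766
667,0.03597149213708585
668,0.05798008055675238
669,0.08143326244251951
670,0.14216619872324054
671,0.17628022691492584
672,0.26149624756962114
673,0.3317200259218773
674,0.4387582416608375
675,0.5426762915104663
676,0.6665728708677265
677,0.7405692621490487
678,0.8235523334394718
679,0.874385332845666
680,0.8914119230568083
681,0.8843903359045386
682,0.8133758506111328
683,0.7321181420704647
684,0.6478672779748336
685,0.5511586609937184
686,0.4198921178628037
687,0.323245260606094
688,0.2732786519843813
689,0.1820907158017282
690,0.11902028492550094
691,0.07681283275993948
692,0.0543250737250986
693,0.03248320643882497
694,0.010060466362543161
695,0.008703607737316136
696,0.010498537681832941
697,0.013202452078659558
698,0.01938265323075017
699,0.007302649841015727
700,0
701,0.007636475481385729
702,0.02761783124547613
703,0
704,0
705,0
706,0
707,0.008400337455448215
708,0
709,0.0032759280023228706
710,0.0018049254778696798
711,0
712,0
713,0.003269972933472239
714,0
715,0
716,0
717,0.014835303351225515
718,0
719,0
720,0.007817117260184534
721,0
722,0.003825444100775564
723,0
724,0
725,0.005813990710414262
726,0.0031600381445930207
727,0.0016833078314070502
728,0
729,0.012993289110787452
730,0.008175951599342956
731,0
732,0
733,0.01481779084924409
734,0
735,0.03311937945078384
736,0.007893888439462158
737,0.002105479876575156
738,0
739,0
740,0.006835453383309378
741,0.0027658195758770605
742,0.004261204745122537
743,0.0036748816020368297
744,0
745,0.007138561191834662
746,0.00752087375343224
747,0.004783157788421219
748,0.01057930608967538
749,0
750,0.014183806911308144
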