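wavelength_nm,mua_oxy,mua_deoxy
440,315.8614,474.5409
442,318.9816,464.9949
444,320.8685,453.5891
446,321.5,440.4713
448,320.8685,425.8081
450,318.9816,409.7817
452,315.8614,392.586
454,311.5446,374.4226
456,306.0814,355.497
458,299.5347,336.0149
460,291.9789,316.1785
462,283.4984,296.1829
464,274.186,276.2135
466,264.1415,256.4431
468,253.4697,237.0299
470,242.2783,218.1155
472,230.6768,199.8241
474,218.7743,182.2615
476,206.6777,165.515
478,194.4907,149.6533
480,182.3118,134.7272
482,170.2336,120.7706
484,158.3413,107.8014
486,146.7124,95.8233
488,135.4156,84.8271
490,124.5107,74.7924
492,114.0484,65.6901
494,104.0698,57.4835
496,94.6076,50.131
498,85.6853,43.5879
500,77.3188,37.8087
502,69.5167,32.7489
504,62.2821,28.3673
506,55.6146,24.6283
508,49.5143,21.5037
510,43.9865,18.9743
512,39.0498,17.0318
514,34.7463,15.6791
516,31.1525,14.9309
518,28.3889,14.8122
520,26.6236,15.3566
522,26.0621,16.6027
524,26.9178,18.5885
526,29.36,21.3455
528,33.4446,24.891
530,39.0391,29.2199
532,45.7672,34.2969
534,52.9964,40.0498
536,59.8903,46.3647
538,65.5254,53.084
540,69.0553,60.0088
542,69.8802,66.905
544,67.776,73.5138
546,62.944,79.5656
548,55.9673,84.7968
550,47.6916,88.9681
552,39.0693,91.8812
554,31.0157,93.3944
556,24.3146,93.4335
558,19.5817,91.9974
560,17.2689,89.1582
562,17.668,85.0553
564,20.8779,79.8841
566,26.721,73.8808
568,34.6404,67.3049
570,43.6439,60.4209
572,52.3691,53.482
574,59.3056,46.7148
576,63.1352,40.3094
578,63.0787,34.4128
580,59.1135,29.1265
582,51.9664,24.5079
584,42.8825,20.575
586,33.265,17.3128
588,24.3239,14.6812
590,16.8511,12.6224
592,11.1651,11.0688
594,7.1964,9.9488
596,4.643,9.1923
598,3.1237,8.7336
600,2.2855,8.5143
602,1.856,8.4843
604,1.6513,8.6017
606,1.5604,8.8325
608,1.5228,9.1499
610,1.5082,9.5333
612,1.5029,9.9667
614,1.501,10.4382
616,1.5004,10.9389
618,1.5002,11.4618
620,1.5001,12.0018
622,1.5001,12.5544
624,1.5001,13.1161
626,1.5,13.6836
628,1.5,14.254
630,1.5,14.8244
632,1.5,15.3919
634,1.5,15.9538
636,1.5,16.507
638,1.5,17.0487
640,1.5,17.576
642,1.5,18.0861
644,1.5,18.576
646,1.5,19.0429
648,1.5,19.484
650,1.5,19.8968
652,1.5,20.2786
654,1.5,20.6272
656,1.5,20.9402
658,1.5,21.2158
660,1.5,21.4521
662,1.5,21.6476
664,1.5,21.801
666,1.5,21.9113
668,1.5,21.9778
670,1.5,22
672,1.5,21.9778
674,1.5,21.9113
676,1.5,21.801
678,1.5,21.6476
680,1.5,21.4521
682,1.5,21.2158
684,1.5,20.9402
686,1.5,20.6272
688,1.5,20.2786
690,1.5,19.8968
692,1.5,19.484
694,1.5,19.0429
696,1.5,18.576
698,1.5,18.0861
700,1.5,17.576
702,1.5,17.0486
704,1.5,16.5069
706,1.5,15.9535
708,1.5,15.3915
710,1.5,14.8236
712,1.5,14.2525
714,1.5,13.6809
716,1.5,13.1112
718,1.5,12.5458
720,1.5,11.987
722,1.5,11.4368
724,1.5,10.8972
726,1.5,10.3697
728,1.5,9.8561
730,1.5,9.3576
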