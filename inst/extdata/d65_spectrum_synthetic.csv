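wavelength_nm,radiance
390,1.073639
395,1.082654
400,1.090673
405,1.097725
410,1.103838
415,1.109044
420,1.113373
425,1.116857
430,1.119527
435,1.121416
440,1.122555
445,1.122977
450,1.122712
455,1.121793
460,1.120251
465,1.118115
470,1.115416
475,1.112182
480,1.108442
485,1.104225
490,1.099556
495,1.094462
500,1.088968
505,1.0831
510,1.07688
515,1.070332
520,1.063478
525,1.056338
530,1.048934
535,1.041286
540,1.033411
545,1.025328
550,1.017054
555,1.008606
560,1
565,0.9912503
570,0.9823715
575,0.9733774
580,0.9642809
585,0.9550945
590,0.9458298
595,0.9364981
600,0.9271099
605,0.9176753
610,0.9082037
615,0.8987042
620,0.8891852
625,0.8796547
630,0.8701202
635,0.8605889
640,0.8510674
645,0.8415621
650,0.8320789
655,0.8226232
660,0.8132003
665,0.8038149
670,0.7944718
675,0.7851749
680,0.7759284
685,0.7667358
690,0.7576005
695,0.7485257
700,0.7395143
705,0.7305689
710,0.721692
715,0.7128859
720,0.7041526
725,0.695494
730,0.6869118
735,0.6784076
740,0.6699826
745,0.6616382
750,0.6533755
755,0.6451953
760,0.6370986
765,0.629086
770,0.6211582
775,0.6133157
780,0.6055588
785,0.597888
790,0.5903033
795,0.582805
800,0.5753931
805,0.5680676
810,0.5608285
815,0.5536755
820,0.5466086
825,0.5396274
830,0.5327317
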