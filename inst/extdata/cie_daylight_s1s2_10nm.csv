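wavelength_nm,s1,s2
380,38.5,3.0
390,35.0,1.2
400,43.4,-1.1
410,46.3,-0.5
420,43.9,-0.7
430,37.1,-1.2
440,36.7,-2.6
450,35.9,-2.9
460,32.6,-2.8
470,27.9,-2.6
480,24.3,-2.6
490,20.1,-1.8
500,16.2,-1.5
510,13.2,-1.3
520,8.6,-1.2
530,6.1,-1.0
540,4.2,-0.5
550,1.9,-0.3
560,0.0,0.0
570,-1.6,0.2
580,-3.5,0.5
590,-3.5,2.1
600,-5.8,3.2
610,-7.2,4.1
620,-8.6,4.7
630,-9.5,5.1
640,-10.9,6.7
650,-10.7,7.3
660,-12.0,8.6
670,-14.0,9.8
680,-13.6,10.2
690,-12.0,8.3
700,-13.3,9.6
710,-12.9,8.5
720,-10.6,7.0
730,-11.6,7.6
740,-12.2,8.0
750,-10.2,6.7
760,-7.8,5.2
770,-11.2,7.4
780,-10.4,6.8
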