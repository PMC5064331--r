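mz	name	polarity
600.5	Cer 39:4-H-	-
646.5	Cer N24:1-H-	-
647.5	PA 32:0-H-	-
767.6	PE 38:4-H-	-
774.6	PE 39:7-H-/PPE 40:6-H-	-
778.6	PE 39:5-H-/PPE 40:4-H-	-
779.6	PG 37:6-H-	-
786.6	PS 36:2-H-	-
789.6	SM 36:1-H-	-
791.6	PE 40:6-H-	-
794.6	PE 40:4-H-	-
795.7	PG 38:5-H-/PA 44:10-H-	-
796.6	PE 40:3-H-	-
797.7	PG 38:4-H-	-
810.6	PS 38:4-H-	-
885.6	PI 38:4-H-	-
906.7	SF 24:0 (0H)-H-	-
918.7	SF 26:0 (0H)-H-	-
1574.0	GM1 d20:1/18:0-H-	-
706.5	PC 30:0+H+	+
718.6	PE 34:1+H+	+
720.6	PE 34:0+H+	+
753.7	SM 36:1+Na+	+
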