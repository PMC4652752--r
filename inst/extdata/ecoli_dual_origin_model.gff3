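##gff-version 3
##sequence-region chromosome 1 4640000
chromosome	repliprofile	origin	3923001	3923001	.	*	.	Name=oriC
chromosome	repliprofile	origin	344001	344001	.	*	.	Name=oriZ
chromosome	repliprofile	dif	1589001	1589001	.	*	.	Name=dif
chromosome	repliprofile	ter	1247001	1247001	.	*	.	Name=terE;block=blocks_counterclockwise;efficiency=1
chromosome	repliprofile	ter	1280001	1280001	.	*	.	Name=terD;block=blocks_counterclockwise;efficiency=1
chromosome	repliprofile	ter	1342001	1342001	.	*	.	Name=terA;block=blocks_counterclockwise;efficiency=1
chromosome	repliprofile	ter	1610001	1610001	.	*	.	Name=terC;block=blocks_clockwise;efficiency=1
chromosome	repliprofile	ter	1682001	1682001	.	*	.	Name=terB;block=blocks_clockwise;efficiency=1
chromosome	repliprofile	ter	2318001	2318001	.	*	.	Name=terF;block=blocks_clockwise;efficiency=1
chromosome	repliprofile	ter	2376001	2376001	.	*	.	Name=terG;block=blocks_clockwise;efficiency=1
chromosome	repliprofile	ter	2440001	2440001	.	*	.	Name=terH;block=blocks_clockwise;efficiency=1
chromosome	repliprofile	ter	3254001	3254001	.	*	.	Name=terI;block=blocks_clockwise;efficiency=1
chromosome	repliprofile	ter	570001	570001	.	*	.	Name=terJ;block=blocks_counterclockwise;efficiency=1
chromosome	repliprofile	rrn	226001	234000	.	+	.	Name=rrnH;head_on_factor=0.25;codirectional_factor=0.9
chromosome	repliprofile	rrn	2726001	2734000	.	-	.	Name=rrnG;head_on_factor=0.25;codirectional_factor=0.9
chromosome	repliprofile	rrn	3423001	3431000	.	-	.	Name=rrnD;head_on_factor=0.25;codirectional_factor=0.9
chromosome	repliprofile	rrn	3941001	3949000	.	+	.	Name=rrnC;head_on_factor=0.25;codirectional_factor=0.9
chromosome	repliprofile	rrn	4033001	4041000	.	+	.	Name=rrnA;head_on_factor=0.25;codirectional_factor=0.9
chromosome	repliprofile	rrn	4164001	4172000	.	+	.	Name=rrnB;head_on_factor=0.25;codirectional_factor=0.9
chromosome	repliprofile	rrn	4205001	4213000	.	+	.	Name=rrnE;head_on_factor=0.25;codirectional_factor=0.9
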