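@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:100000
@SQ	SN:chrM	LN:16000
p1	99	chr1	1001	60	50M	=	1101	150	*	*
p1	147	chr1	1101	60	50M	=	1001	-150	*	*
p2	99	chr1	5001	60	50M	=	5151	200	*	*
p2	147	chr1	5151	60	50M	=	5001	-200	*	*
m1	99	chrM	201	60	50M	=	301	150	*	*
m1	147	chrM	301	60	50M	=	201	-150	*	*
orphan	0	chr1	9001	30	50M	*	0	0	*	*
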