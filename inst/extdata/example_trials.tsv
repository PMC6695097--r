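subject_id	group	condition	target	response	masker_id
ex01	control	1T	he BROKE his LEG		talker1
ex01	control	1T	the DAUGHTER SET the TABLE	can go very fast	talker1
ex01	control	1T	a MAN is TURNING the FAUCET	is turning the faucet	talker1
ex02	control	1T	a MAN is TURNING the FAUCET	is turning the faucet	talker1
ex01	control	1T	a MAN is TURNING the FAUCET	a man is turning the faucet trees	talker1
ex01	control	1T	FATHER FORGOT the BREAD	the father forgot the bread	talker1
ex01	control	1T	the BOY HURRIED to SCHOOL	the boy went to school	talker1
ex02	control	1T	a MAN is TURNING the FAUCET	the man is turning the faucet	talker1
ex01	control	1T	the DAUGHTER SET the TABLE	the daughters set the table	talker1
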