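probe_id	symbols
205828_at	MMP3
202274_at	ACTG2
219747_at	NDNF
207172_s_at	CDH11
52255_s_at	COL5A3
204136_at	COL7A1
218002_s_at	CXCL14
214974_x_at	CXCL5
208394_x_at	ESM1
216557_x_at	IGHD;IGHG1
39402_at	IL1B
210302_s_at	MAB21L2
209086_x_at	MCAM
213075_at	OLFML2A
206637_at	P2RY14
203708_at	PDE4B
203680_at	PRKAR2B
201404_x_at	PSMB2
209070_s_at	RGS5
205529_s_at	RUNX1T1
215382_x_at	TPSAB1
202112_at	VWF
205990_s_at	WNT5A
213425_at	WNT5A
207117_at	ZNF117
202437_s_at	CYP1B1
202436_s_at	CYP1B1
219873_at	COLEC11
205753_at	CRP
204988_at	FGB
206010_at	HABP2
202376_at	SERPINA3
209875_s_at	SPP1
201666_at	TIMP1
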