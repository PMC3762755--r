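feature_id	direction	source_probes
205828_at	down_in_HM	205828_at
202274_at	down_in_HM	202274_at
219747_at	down_in_HM	219747_at
207172_s_at	down_in_HM	207172_s_at
52255_s_at	down_in_HM	52255_s_at
204136_at	down_in_HM	204136_at
218002_s_at	down_in_HM	218002_s_at
214974_x_at	down_in_HM	214974_x_at
208394_x_at	down_in_HM	208394_x_at
216557_x_at	down_in_HM	216557_x_at
39402_at	down_in_HM	39402_at
210302_s_at	down_in_HM	210302_s_at
209086_x_at	down_in_HM	209086_x_at
213075_at	down_in_HM	213075_at
206637_at	down_in_HM	206637_at
203708_at	down_in_HM	203708_at
203680_at	down_in_HM	203680_at
201404_x_at	down_in_HM	201404_x_at
209070_s_at	down_in_HM	209070_s_at
205529_s_at	down_in_HM	205529_s_at
215382_x_at	down_in_HM	215382_x_at
202112_at	down_in_HM	202112_at
205990_s_at	down_in_HM	205990_s_at
213425_at	down_in_HM	213425_at
207117_at	down_in_HM	207117_at
202437_s_at	up_in_HM	202437_s_at
202436_s_at	up_in_HM	202436_s_at
219873_at	up_in_HM	219873_at
205753_at	up_in_HM	205753_at
204988_at	up_in_HM	204988_at
206010_at	up_in_HM	206010_at
202376_at	up_in_HM	202376_at
209875_s_at	up_in_HM	209875_s_at
201666_at	up_in_HM	201666_at
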