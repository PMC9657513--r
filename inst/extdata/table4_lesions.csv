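case,lesion_id,trend,clinical_response,area_change_frac,transient_event
1,IH01,negative,positive,-0.3,regrowth after treatment discontinuation (2nd month)
2,IH02,negative,positive,-0.3,none
3,IH03,negative,positive,-0.3,regrowth after treatment discontinuation (1st month)
4,IH04,negative,positive,-0.3,ulceration and regrowth after treatment discontinuation (1st month)
5,IH05,null,positive,-0.5,none
5,IH06,negative,positive,-0.3,none
6,IH07,negative,positive,-0.3,none
6,IH08,negative,positive,-0.3,none
6,IH09,negative,positive,-0.3,none
6,IH10,negative,positive,-0.3,none
6,IH11,negative,positive,-0.3,none
6,IH12,negative,positive,-0.3,none
6,IH13,negative,positive,-0.3,none
7,IH14,negative,positive,-0.3,none
8,IH15,negative,positive,-0.3,none
9,IH16,negative,positive,-0.3,transitory ulceration (5th-7th month)
9,IH17,negative,positive,-0.3,none
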