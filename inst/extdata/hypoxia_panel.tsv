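probeset	symbol	family
202912_at	ADM	hypoxia_panel
217254_s_at	EPO	hypoxia_panel
209328_x_at	HIGD2A	hypoxia_panel
209329_x_at	HIGD2A	hypoxia_panel
218507_at	HILPDA	hypoxia_panel
1554452_a_at	HILPDA	hypoxia_panel
207092_at	LEP	hypoxia_panel
229093_at	NOS3	hypoxia_panel
205581_s_at	NOS3	hypoxia_panel
217112_at	PDGFB	hypoxia_panel
216061_x_at	PDGFB	hypoxia_panel
203400_s_at	TF	hypoxia_panel
212171_x_at	VEGFA	hypoxia_panel
211527_x_at	VEGFA	hypoxia_panel
210513_s_at	VEGFA	hypoxia_panel
203683_s_at	VEGFB	hypoxia_panel
209946_at	VEGFC	hypoxia_panel
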