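exposure	mediator	outcome	te_or	nie_or	nie_or_low	nie_or_high	proportion_pct	proportion_low_pct	proportion_high_pct
bread_white_vs_any_other	insomnia	migraine	1.511462	1.049	1.024	1.075	11.62	3.67	19.58
bread_white_vs_wholemeal_brown	insomnia	migraine	1.42896	1.049	1.025	1.073	13.39	4.3	22.48
bread_wholemeal_vs_white_brown	insomnia	migraine	0.760494	0.948	0.925	0.971	19.59	4.45	34.73
cereal_muesli_vs_any_other	insomnia	migraine	0.651232	0.932	0.901	0.963	16.46	2.92	30
cereal_muesli_vs_any_other	mdd	migraine	0.651232	0.879	0.816	0.948	29.96	5.54	54.38
drinks_usually_with_meals	insomnia	migraine	0.609764	0.922	0.89	0.955	16.42	5.7	27.15
drinks_usually_with_meals	mdd	migraine	0.609764	0.88	0.823	0.941	25.81	8.86	42.77
overall_alcohol_intake	insomnia	migraine	0.740076	0.977	0.961	0.993	7.76	1.16	14.36
overall_alcohol_intake	mdd	migraine	0.740076	0.954	0.922	0.986	15.8	2.91	28.7
red_wine_glasses_per_month	insomnia	migraine	0.648894	0.959	0.937	0.982	9.66	2.47	16.85
red_wine_glasses_per_month	mdd	migraine	0.648894	0.932	0.887	0.979	16.3	3.33	29.27
overall_cheese_intake	insomnia	migraine	0.775472	0.97	0.951	0.99	11.92	0.18	23.67
overall_cheese_intake	mdd	migraine	0.775472	0.952	0.917	0.988	19.24	0.14	38.34
overall_oily_fish_intake	insomnia	migraine	0.735076	0.97	0.951	0.989	10.05	1.13	18.96
bread_white_vs_any_other	insomnia	migraine_without_aura	1.637199	1.068	1.032	1.106	13.38	2.91	23.85
bread_white_vs_wholemeal_brown	insomnia	migraine_without_aura	1.505478	1.068	1.033	1.104	16.06	2.67	29.45
bread_wholemeal_vs_white_brown	insomnia	migraine_without_aura	0.635146	0.928	0.896	0.961	16.5	4.61	28.4
red_wine_glasses_per_month	insomnia	migraine_without_aura	0.542683	0.943	0.912	0.976	9.55	2.19	16.91
red_wine_glasses_per_month	mdd	migraine_without_aura	0.542683	0.909	0.849	0.974	15.56	2.65	28.46
overall_oily_fish_intake	insomnia	migraine_without_aura	0.65074	0.96	0.934	0.986	9.61	0.29	18.94
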