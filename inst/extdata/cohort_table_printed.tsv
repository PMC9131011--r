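label	type	m1	sd1	n1	m2	sd2	n2	pct1	pct2	printed
age_years	t	67.1	12.2	103	62.4	15.6	81			2.3
bmi	t	25.7	5.2	103	26.2	4.6	81			-0.7
last_antibiotic_months	t	21.9	33.8	103	25.8	37.8	81			-0.7
daily_coffee_cups	t	2.3	1.7	103	3.1	1.8	81			3.0
cleveland_constipation	t	7.2	4.7	103	3.1	2.9	81			6.9
rome_iv_constipation	t	4.4	3.5	103	1.1	1.4	81			7.9
bristol_stool	t	2.8	1.5	103	3.9	1.3	81			4.0
leeds_dyspepsia	t	8.3	7.7	103	4.6	6.1	81			3.5
ipaq_met_min	t	1823.6	1693.6	103	2942.4	2620.9	81			-3.5
sitting_hours	t	6.5	3.5	103	4.8	2.3	81			3.7
crp	t	3.9	10.8	103	2.2	2.5	81			1.4
total_cholesterol	t	4.8	0.9	103	5.2	1.1	81			-2.5
hdl	t	1.4	0.4	103	1.6	0.4	81			-2.2
albumin	t	38.7	3.5	103	39.8	3.1	81			-2.3
beck_depression	t	11.9	8.8	103	5.2	5.5	81			5.9
moca_total	t	24.4	4.8	103	27.6	2.5	81			-5.4
sf36_health_change	t	38.8	21.7	103	50.6	16.3	81			-4.0
sf36_physical	t	51.6	22.7	103	79.9	17.7	81			-9.3
sf36_mental	t	60.9	22.2	103	80.8	17.4	81			-6.6
gender_male	chi2			103			81	56.3	32.1	10.7
functional_constipation	chi2			103			81	78.6	28.4	46.6
chronic_pain	chi2			103			81	72.8	39.5	20.7
alcohol_consumption	chi2			103			81	70.0	87.7	8.7
caffeine_consumption	chi2			103			81	85.4	91.4	1.5
diabetes_history	chi2			103			81	4.9	6.2	0.2
mild_cognitive_impairment	chi2			103			81	48.6	18.5	17.9
able_walk_1km	chi2			103			81	73.8	97.5	19.3
able_climb_stairs	chi2			103			81	86.4	100	11.9
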