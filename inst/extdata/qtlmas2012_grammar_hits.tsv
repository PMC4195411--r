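# Genome-wide significant SNPs from the original GRAMMAR analyses of the
# QTL-MAS 2012 workshop dataset (three traits and two trait principal
# components).  Positions in Mb; effect is the per-dose regression
# coefficient on the trait scale; chi2 is the 1-df association statistic.
label	chr	pos	effect	se	chi2
trait1	1	84.05	14.81	3.45	18.39
trait1	1	84.10	-13.97	3.48	16.09
trait1	4	24.85	-14.74	3.84	14.70
trait1	4	24.90	23.06	3.47	44.23
trait1	4	25.00	12.64	3.40	13.83
trait1	4	25.25	13.58	3.97	11.69
trait2	1	14.60	-0.96	0.19	26.20
trait2	1	14.70	0.62	0.18	11.80
trait2	1	14.75	0.65	0.18	12.61
trait2	1	14.85	0.87	0.22	16.28
trait2	3	2.15	-1.04	0.27	14.39
trait2	4	24.85	-0.83	0.21	16.37
trait2	4	24.90	1.40	0.19	57.50
trait2	4	25.00	0.77	0.18	17.93
trait2	4	25.25	0.73	0.21	11.83
trait3	1	58.00	-0.0021	0.0006	13.17
trait3	1	58.25	-0.0018	0.0005	10.96
trait3	1	58.85	0.0013	0.0004	10.61
trait3	1	84.05	-0.0025	0.0004	39.27
trait3	1	84.10	0.0024	0.0004	37.30
trait3	1	84.80	0.0017	0.0005	10.93
trait3	1	84.90	-0.0019	0.0004	23.59
trait3	2	79.15	-0.0015	0.0004	14.41
trait3	2	79.20	-0.0023	0.0004	29.32
trait3	3	2.15	-0.0022	0.0006	14.26
trait3	3	36.85	-0.0014	0.0004	12.50
pc1	1	14.60	-0.07	0.02	12.98
pc1	1	84.05	0.07	0.02	14.30
pc1	1	84.10	-0.07	0.02	12.23
pc1	4	24.85	-0.09	0.02	16.08
pc1	4	24.90	0.14	0.02	49.33
pc1	4	25.00	0.07	0.02	15.27
pc1	4	25.25	0.08	0.02	12.42
pc2	1	14.60	-0.07	0.02	15.50
pc2	1	14.70	0.05	0.02	10.35
pc2	1	84.05	-0.09	0.02	30.50
pc2	1	84.10	0.09	0.02	29.76
pc2	1	84.90	-0.07	0.02	19.80
pc2	2	79.15	-0.07	0.02	16.33
pc2	2	79.20	-0.09	0.02	26.57
pc2	3	2.15	-0.11	0.02	21.32
pc2	3	2.30	-0.08	0.02	10.40
pc2	3	36.85	-0.06	0.02	10.57
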