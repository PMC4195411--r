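# SNPs flagged by the original multivariate Bayesian analysis of the
# QTL-MAS 2012 workshop dataset.  Positions in Mb; Bayes factors on the
# log10 scale.
chr	pos	log10_bf
1	14.60	4.3952
1	84.05	8.0932
1	84.10	7.6726
1	84.90	3.9167
2	79.15	3.8483
2	79.20	7.2374
3	2.15	4.5439
4	24.90	10.283
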