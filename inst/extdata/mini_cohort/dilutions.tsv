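assay_id	copies	cq
sense	1e+05	21.3859
sense	1e+05	21.1673
sense	10000	24.8332
sense	10000	24.6365
sense	1000	27.9885
sense	1000	27.8324
sense	100	31.378
sense	100	31.3983
sense	10	34.5592
sense	10	34.7194
sense	1	38.0298
sense	1	37.822
antisense	1e+05	21.3145
antisense	1e+05	21.2796
antisense	10000	24.5978
antisense	10000	24.6289
antisense	1000	27.8497
antisense	1000	28.1242
antisense	100	31.341
antisense	100	31.1756
antisense	10	34.8657
antisense	10	34.4706
antisense	1	37.9605
antisense	1	37.9784
bs_actin	1e+05	21.3926
bs_actin	1e+05	21.1678
bs_actin	10000	24.6057
bs_actin	10000	24.8111
bs_actin	1000	28.2048
bs_actin	1000	27.9085
bs_actin	100	31.3479
bs_actin	100	31.4762
bs_actin	10	34.6574
bs_actin	10	34.6224
bs_actin	1	38.3861
bs_actin	1	38.1319
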