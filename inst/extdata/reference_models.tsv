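model_id	label	b0	b1_area	b2_tbr	b3_fwhm	r_squared	shrinkage	selection_order	beta_x2	pr2_x2	beta_x3	pr2_x3	beta_x1	pr2_x1
discovery_st	Discovery ST	90.68	NA	-62.44	1.05	0.91	-0.008	x2;x3_fwhm	-0.91	0.85	0.23	0.06	NA	NA
discovery_ste	Discovery STE	88.68	NA	-59.39	1.03	0.87	0.004	x2;x3_fwhm	-0.90	0.82	0.23	0.05	NA	NA
discovery_600	Discovery 600	93.52	NA	-64.38	0.99	0.92	0.000	x2;x3_fwhm	-0.93	0.88	0.20	0.04	NA	NA
discovery_690	Discovery 690	63.04	-0.015	-40.51	1.92	0.74	0.007	x2;x3_fwhm;x1_area	-0.61	0.40	0.54	0.29	0.22	0.05
biograph_hirez	Biograph Hi-REZ	88.19	NA	-56.18	0.67	0.92	-0.012	x2;x3_fwhm	-0.95	0.91	0.10	0.01	NA	NA
biograph_truev	Biograph TRUEV	90.43	NA	-61.86	0.95	0.89	-0.013	x2;x3_fwhm	-0.91	0.85	0.19	0.04	NA	NA
gemini_xl	Gemini XL	92.04	0.0025	-59.15	NA	0.82	0.067	x2;x1_area	-0.89	0.74	NA	NA	0.27	0.08
gemini_tf	Gemini TF	88.57	0.0027	-57.44	NA	0.84	-0.009	x2;x1_area	-0.88	0.76	NA	NA	0.28	0.08
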