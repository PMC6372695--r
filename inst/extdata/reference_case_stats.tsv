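case_id	group	curvature_mean	curvature_sd	curvature_n	orphan_curvature_mean	orphan_curvature_sd	orphan_curvature_n	torsion_mean	torsion_sd	torsion_n
S1	schizophrenia	0.46	0.28	523	0.58	0.30	288	-0.03	0.35	513
S2	schizophrenia	0.47	0.32	754	0.59	0.34	450	-0.02	0.37	742
S3	schizophrenia	0.60	0.34	435	0.78	0.32	238	0.01	0.41	426
S4	schizophrenia	0.71	0.36	880	0.79	0.36	700	0.00	0.33	873
N1	control	0.33	0.22	415	0.38	0.21	154	0.02	0.44	389
N2	control	0.44	0.21	731	0.49	0.21	422	0.01	0.32	721
N3	control	0.37	0.21	491	0.46	0.21	289	0.01	0.27	484
N4	control	0.41	0.23	432	0.48	0.24	252	-0.03	0.34	426
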