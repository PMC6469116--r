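# Synthetic stand-in for a 92-transcript ERCC spike-in mix.
# Concentrations are log-spaced over 6 decades (arbitrary units; only ratios matter);
# lengths are representative 250-2000 nt. Not the commercial ERCC concentration sheet.
transcript_id	length_nt	concentration
ERCC-00002	1575	1.00000e+02
ERCC-00004	300	8.59144e+01
ERCC-00006	350	7.38128e+01
ERCC-00008	1650	6.34158e+01
ERCC-00010	1900	5.44833e+01
ERCC-00012	1350	4.68090e+01
ERCC-00014	600	4.02157e+01
ERCC-00016	1050	3.45511e+01
ERCC-00018	775	2.96843e+01
ERCC-00020	1300	2.55031e+01
ERCC-00022	1925	2.19109e+01
ERCC-00024	825	1.88246e+01
ERCC-00026	1425	1.61730e+01
ERCC-00028	1800	1.38950e+01
ERCC-00030	350	1.19378e+01
ERCC-00032	500	1.02563e+01
ERCC-00034	500	8.81160e+00
ERCC-00036	1425	7.57044e+00
ERCC-00038	1425	6.50409e+00
ERCC-00040	700	5.58795e+00
ERCC-00042	725	4.80086e+00
ERCC-00044	1725	4.12463e+00
ERCC-00046	250	3.54365e+00
ERCC-00048	1575	3.04450e+00
ERCC-00050	425	2.61567e+00
ERCC-00052	1000	2.24723e+00
ERCC-00054	1750	1.93070e+00
ERCC-00056	375	1.65875e+00
ERCC-00058	1500	1.42510e+00
ERCC-00060	550	1.22437e+00
ERCC-00062	1050	1.05191e+00
ERCC-00064	1050	9.03741e-01
ERCC-00066	850	7.76444e-01
ERCC-00068	1125	6.67077e-01
ERCC-00070	1850	5.73115e-01
ERCC-00072	1275	4.92388e-01
ERCC-00074	1775	4.23032e-01
ERCC-00076	575	3.63446e-01
ERCC-00078	875	3.12252e-01
ERCC-00080	1200	2.68270e-01
ERCC-00082	350	2.30482e-01
ERCC-00084	1800	1.98017e-01
ERCC-00086	1025	1.70125e-01
ERCC-00088	1325	1.46162e-01
ERCC-00090	1325	1.25574e-01
ERCC-00092	325	1.07886e-01
ERCC-00094	425	9.26900e-02
ERCC-00096	700	7.96341e-02
ERCC-00098	1900	6.84171e-02
ERCC-00100	325	5.87802e-02
ERCC-00102	1675	5.05006e-02
ERCC-00104	700	4.33873e-02
ERCC-00106	1950	3.72759e-02
ERCC-00108	1600	3.20254e-02
ERCC-00110	250	2.75144e-02
ERCC-00112	1325	2.36389e-02
ERCC-00114	1550	2.03092e-02
ERCC-00116	450	1.74485e-02
ERCC-00118	1000	1.49908e-02
ERCC-00120	700	1.28792e-02
ERCC-00122	1375	1.10651e-02
ERCC-00124	1550	9.50653e-03
ERCC-00126	1600	8.16748e-03
ERCC-00128	950	7.01704e-03
ERCC-00130	500	6.02865e-03
ERCC-00132	775	5.17947e-03
ERCC-00134	400	4.44991e-03
ERCC-00136	1075	3.82312e-03
ERCC-00138	800	3.28461e-03
ERCC-00140	725	2.82195e-03
ERCC-00142	1300	2.42446e-03
ERCC-00144	500	2.08296e-03
ERCC-00146	425	1.78956e-03
ERCC-00148	1525	1.53749e-03
ERCC-00150	1725	1.32093e-03
ERCC-00152	1875	1.13487e-03
ERCC-00154	775	9.75014e-04
ERCC-00156	400	8.37678e-04
ERCC-00158	1225	7.19686e-04
ERCC-00160	550	6.18314e-04
ERCC-00162	1000	5.31220e-04
ERCC-00164	1300	4.56395e-04
ERCC-00166	1750	3.92109e-04
ERCC-00168	1850	3.36878e-04
ERCC-00170	1075	2.89427e-04
ERCC-00172	1500	2.48659e-04
ERCC-00174	1725	2.13634e-04
ERCC-00176	1100	1.83542e-04
ERCC-00178	700	1.57689e-04
ERCC-00180	1825	1.35478e-04
ERCC-00182	1625	1.16395e-04
ERCC-00184	1600	1.00000e-04
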