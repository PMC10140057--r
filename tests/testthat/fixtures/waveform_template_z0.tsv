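1.50958182556e-04	2.99347977215e-04	5.75703742964e-04	1.07380354702e-03	1.94246709776e-03	3.40788996994e-03	5.79856477906e-03	9.56882293189e-03	1.53143856364e-02	2.37707944022e-02	3.57841634162e-02	5.22445625474e-02	7.39766024911e-02	1.01589944295e-01	1.35303838858e-01	1.74772287699e-01	2.18946536408e-01	2.66015316886e-01	3.13457210021e-01	3.58222565511e-01	3.97036717742e-01	4.26787272858e-01	4.44933702764e-01	4.49864997762e-01	4.41135653239e-01	4.19532076134e-01	3.86955691594e-01	3.46146833044e-01	3.00304985426e-01	2.52678201799e-01	2.06194021499e-01	1.63187698075e-01	1.25256946292e-01	9.32436528546e-02	6.73193314475e-02	4.71371554282e-02	3.20103243198e-02	2.10824342449e-02	1.34668265905e-02	8.34501359676e-03	5.02788974170e-03	3.00193051089e-03	2.02122385911e-03	2.39094921809e-03	5.72343139791e-03	1.65160899118e-02	4.45360187408e-02	1.06727060963e-01	2.25413739206e-01	4.18988838457e-01	6.85208990634e-01	9.85866449115e-01	1.24790711174e+00	1.38967901314e+00	1.36149195655e+00	1.17350684485e+00	8.89879639463e-01	5.93702391645e-01	3.48544203874e-01	1.80148269321e-01	8.21616292929e-02	3.34125650690e-02	1.27389459771e-02	5.60131720878e-03	4.24126093515e-03	5.35721465898e-03	7.90913674011e-03	1.18183213394e-02	1.73835459426e-02	2.50658105686e-02	3.54122618392e-02	4.90148131112e-02	6.64660777846e-02	8.83021980577e-02	1.14932199710e-01	1.46558382531e-01	1.83095785471e-01	2.24101504467e-01	2.68726153885e-01	3.15699461122e-01	3.63359471083e-01	4.09730099106e-01	4.52645276495e-01	4.89910623014e-01	5.19486732644e-01	5.39673140976e-01	5.49270010681e-01	5.47696179435e-01	5.35047420879e-01	5.12086796650e-01	4.80168450976e-01	4.41105431073e-01	3.96999471151e-01	3.50054924315e-01	3.02399587506e-01	2.55932204421e-01	2.12210769567e-01	1.72388639869e-01	1.37198260746e-01	1.06976234903e-01	8.17193213200e-02	6.11590785727e-02	4.48431235853e-02	3.22128773103e-02	2.26705429167e-02	1.56312267464e-02	1.05590037749e-02	6.98797861413e-03	4.53084212013e-03	2.87809437773e-03	1.79114140315e-03	1.09207748805e-03	6.52342654311e-04	3.81765639932e-04	2.18885321937e-04	1.22951882055e-04	6.76631889854e-05	3.64811469311e-05	1.92700678976e-05	9.97233239911e-06	5.05602237379e-06	2.51142358310e-06	1.22216456848e-06	5.82690784871e-07	2.72173194495e-07	1.24552167973e-07	5.58413580827e-08	2.45278449676e-08
5.36833737764e-04	9.34692447968e-04	1.58754900881e-03	2.63035898443e-03	4.25140405014e-03	6.70315428069e-03	1.03099254260e-02	1.54689668196e-02	2.26410501765e-02	3.23266947067e-02	4.50251855934e-02	6.11757351315e-02	8.10834758113e-02	1.04837098591e-01	1.32229118970e-01	1.62692933787e-01	1.95271900211e-01	2.28633723616e-01	2.61138137226e-01	2.90957656121e-01	3.16241420756e-01	3.35302808221e-01	3.46804803642e-01	3.49914946166e-01	3.44404928296e-01	3.30678300483e-01	3.09721612545e-01	2.82987206362e-01	2.52226995860e-01	2.19303623767e-01	1.86007100960e-01	1.53901451346e-01	1.24218243000e-01	9.78042043483e-02	7.51206167690e-02	5.62846889118e-02	4.11387537469e-02	2.93321318608e-02	2.04024447344e-02	1.38474085448e-02	9.18466079452e-03	6.00763626386e-03	4.06394931801e-03	3.41306609933e-03	4.75529603494e-03	1.00254924498e-02	2.32274470402e-02	5.11590853948e-02	1.03193354490e-01	1.89003405989e-01	3.13692049823e-01	4.71559503291e-01	6.41964846905e-01	7.91428601495e-01	8.83555009634e-01	8.93256897753e-01	8.17790942345e-01	6.78013102771e-01	5.09075711569e-01	3.46201486660e-01	2.13325630557e-01	1.19252551821e-01	6.07440105311e-02	2.86507734190e-02	1.32683900022e-02	7.17769358084e-03	5.81847351320e-03	6.87730811567e-03	9.42383950225e-03	1.32464187813e-02	1.84648480320e-02	2.53411857897e-02	3.41939332504e-02	4.53534488205e-02	5.91282058584e-02	7.57704560631e-02	9.54389410683e-02	1.18160357519e-01	1.43793233585e-01	1.71998861767e-01	2.02224217981e-01	2.33701352257e-01	2.65466518970e-01	2.96400378326e-01	3.25288134035e-01	3.50895790126e-01	3.72056214768e-01	3.87756813513e-01	3.97219702001e-01	3.99965556970e-01	3.95853851721e-01	3.85094774358e-01	3.68231421697e-01	3.46094368716e-01	3.19733903774e-01	2.90337622645e-01	2.59142361197e-01	2.27349485481e-01	1.96051427462e-01	1.66175315050e-01	1.38446978436e-01	1.13375945482e-01	9.12596567097e-02	7.22033268543e-02	5.61508138795e-02	4.29215474679e-02	3.22489186081e-02	2.38163612938e-02	1.72884529620e-02	1.23355160969e-02	8.65125244515e-03	5.96377313915e-03	4.04095219947e-03	2.69132893581e-03	1.76185562462e-03	1.13369001792e-03	7.17032427906e-04	4.45762715662e-04	2.72388741351e-04	1.63604420631e-04	9.65876021427e-05	5.60490432675e-05	3.19694740881e-05	1.79235177047e-05	9.87714604410e-06	5.35007869830e-06	2.84845481409e-06	1.49066126883e-06
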