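sensor,product,transform,lambda1,lambda2,lambda3,lambda4,beta0,beta1,beta2,beta3,beta4,threshold,note
modis,ag275,log_log,443,488,531,547,0.089,-0.540,-1.142,3.444,-1.875,4.825,
modis,ag355,log_log,443,488,531,547,-2.246,-1.186,-0.558,2.912,-1.336,0.9104,
modis,ag380,log_log,443,488,531,547,-2.263,-0.300,-1.882,3.831,-1.787,0.4341,
modis,ag412,log_log,443,488,531,547,-2.535,-0.563,-1.294,1.606,0.170,0.36419,
modis,ag443,log_log,443,488,531,547,-3.287,-0.727,-0.922,1.278,0.261,0.1984,
modis,ag488,log_log,443,488,531,547,-3.722,-0.377,-1.429,1.424,0.300,0.1114,
seawifs,ag275,log_log,443,490,510,555,-2.477,-2.880,2.225,0.480,-0.252,4.825,
seawifs,ag355,log_log,443,490,510,555,-4.199,-2.563,1.214,0.955,-0.040,0.9104,
seawifs,ag380,log_log,443,490,510,555,-4.544,-1.808,0.175,1.181,0.001,0.4341,
seawifs,ag412,log_log,443,490,510,555,-6.004,-0.861,-0.006,-0.346,0.515,0.36419,
seawifs,ag443,log_log,443,490,510,555,-6.410,-0.743,-0.145,-0.367,0.547,0.1984,
seawifs,ag490,log_log,443,490,510,555,-7.014,-0.736,0.142,-0.796,0.678,0.1114,
modis,sg275-295,log_log,443,488,531,547,-3.289,0.270,-0.335,1.051,-0.921,,
modis,sg290-600,log_log,443,488,531,547,-3.471,0.127,-0.251,1.025,-0.843,,
modis,sg300-600,log_log,443,488,531,547,-3.607,0.044,-0.153,0.881,-0.722,,
modis,sg350-400,log_log,443,488,531,547,-3.924,-0.242,0.055,0.935,-0.710,,
modis,sg350-600,log_log,443,488,531,547,-3.908,-0.204,0.098,0.609,-0.463,,
modis,sg380-600,log_log,443,488,531,547,-3.912,-0.152,0.127,0.236,-0.173,,
modis,sg412-600,log_log,443,488,531,547,-4.219,-0.180,0.137,0.168,-0.131,,
modis,sg412-555,log_log,443,488,531,547,4.195,-0.162,0.147,0.096,-0.084,,intercept positive as published
seawifs,sg275-295,log_log,443,490,510,555,-3.012,0.427,-0.459,0.357,-0.228,,
seawifs,sg290-600,log_log,443,490,510,555,-3.425,0.131,-0.085,0.145,-0.130,,
seawifs,sg300-600,log_log,443,490,510,555,-3.615,0.004,0.014,0.160,-0.129,,
seawifs,sg350-400,log_log,443,490,510,555,-3.968,-0.298,0.178,0.301,-0.150,,
seawifs,sg350-600,log_log,443,490,510,555,-4.058,-0.288,0.091,0.356,-0.138,,
seawifs,sg380-600,log_log,443,490,510,555,-4.072,-0.226,0.088,0.208,-0.051,,
seawifs,sg412-600,log_log,443,490,510,555,-4.498,-0.466,0.690,-0.202,-0.015,,
seawifs,sg412-555,log_log,443,490,510,555,-4.533,-0.455,0.683,-0.214,-0.012,,
modis,doc_mlr1,log_log,443,488,531,547,4.923,0.641,-2.424,3.503,1.692,,ln-response DOC from reflectance alone; weakly constrained
seawifs,doc_mlr1,log_log,443,490,510,555,5.272,0.526,-2.982,2.623,0.089,,ln-response DOC from reflectance alone; weakly constrained
any,doc_mlr2,linear,,,,,192.718,26.790,-3.558,,,,predictors ag355 (m^-1) and salinity (psu); linear response
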