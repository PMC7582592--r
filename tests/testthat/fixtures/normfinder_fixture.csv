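mirna_id,CTR_01,CTR_02,CTR_03,CTR_04,CTR_05,D_01,D_02,D_03,D_04,D_05,DME_01,DME_02,DME_03,DME_04,DME_05
fix-miR-1,24.765,23.734,24.343,24.727,23.465,23.564,23.51,23.266,24.141,24.323,24.666,24.637,23.429,24.91,23.66
fix-miR-2,26.887,25.677,25.528,25.963,25.841,25.478,24.9,25.219,26.404,26.895,26.471,26.445,24.969,27.062,25.475
fix-miR-3,28.833,27.973,28.636,28.513,27.596,27.055,27.199,27.015,27.316,28.337,28.662,28.414,27.726,28.706,27.256
fix-miR-4,25.783,24.6,25.614,25.609,24.576,24.634,24.277,24.586,25.169,25.345,25.656,25.658,24.516,25.326,24.724
fix-miR-5,30.586,29.817,30.5,31.115,29.226,29.96,29.535,29.582,30.316,30.543,31.788,31.995,31.185,32.138,31.004
fix-miR-6,28.161,27.376,27.696,26.987,25.565,27.78,26.64,26.341,26.943,26.371,28.09,27.349,26.352,28.671,27.324
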