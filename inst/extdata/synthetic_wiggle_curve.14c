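# SYNTHETIC calibration curve (not a measured dataset)
# analytic wiggle fixture: offset 1850 yr, 60 yr amplitude, 500 yr period, 40 yr error
# cal BP, 14C age BP, 1-sigma error (yr)
12000,10150.0,40
12020,10184.9,40
12040,10218.9,40
12060,10251.1,40
12080,10280.7,40
12100,10307.1,40
12120,10329.9,40
12140,10348.9,40
12160,10364.3,40
12180,10376.2,40
12200,10385.3,40
12220,10392.1,40
12240,10397.5,40
12260,10402.5,40
12280,10407.9,40
12300,10414.7,40
12320,10423.8,40
12340,10435.7,40
12360,10451.1,40
12380,10470.1,40
12400,10492.9,40
12420,10519.3,40
12440,10548.9,40
12460,10581.1,40
12480,10615.1,40
12500,10650.0,40
12520,10684.9,40
12540,10718.9,40
12560,10751.1,40
12580,10780.7,40
12600,10807.1,40
12620,10829.9,40
12640,10848.9,40
12660,10864.3,40
12680,10876.2,40
12700,10885.3,40
12720,10892.1,40
12740,10897.5,40
12760,10902.5,40
12780,10907.9,40
12800,10914.7,40
12820,10923.8,40
12840,10935.7,40
12860,10951.1,40
12880,10970.1,40
12900,10992.9,40
12920,11019.3,40
12940,11048.9,40
12960,11081.1,40
12980,11115.1,40
13000,11150.0,40
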