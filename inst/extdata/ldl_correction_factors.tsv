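drug	dose	reduction	is_min_dose
atorvastatin	10	0.37	1
atorvastatin	20	0.43	0
atorvastatin	40	0.49	0
atorvastatin	80	0.55	0
simvastatin	10	0.27	1
simvastatin	20	0.32	0
simvastatin	40	0.37	0
simvastatin	80	0.42	0
rosuvastatin	5	0.38	1
rosuvastatin	10	0.43	0
rosuvastatin	20	0.48	0
rosuvastatin	40	0.53	0
pravastatin	10	0.20	1
pravastatin	20	0.24	0
pravastatin	40	0.29	0
fluvastatin	20	0.21	1
fluvastatin	40	0.25	0
fluvastatin	80	0.33	0
ezetimibe	10	0.18	1
atorvastatin+ezetimibe	10	0.50	1
atorvastatin+ezetimibe	20	0.54	0
atorvastatin+ezetimibe	40	0.58	0
simvastatin+ezetimibe	10	0.42	1
simvastatin+ezetimibe	20	0.46	0
simvastatin+ezetimibe	40	0.50	0
rosuvastatin+ezetimibe	5	0.50	1
rosuvastatin+ezetimibe	10	0.54	0
rosuvastatin+ezetimibe	20	0.57	0
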