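# Synthetic population prior for the uptake component (A2, lambda2) of the
# biexponential organ model. NOT clinical data: calibrated only so that the
# modeled uptake phase peaks before the earliest (2 h) scan time.
organ,A2_MBq,lambda2_per_h
left_kidney,30,2.5
right_kidney,30,2.5
liver,50,3.0
spleen,10,3.0
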