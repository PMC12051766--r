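# Synthetic S-value matrix (Gy per MBq*h) for the four dosimetry organs.
# NOT phantom-derived reference dose factors: magnitudes chosen so typical
# cohort TIAs map to absorbed doses of clinically familiar size.
source,target,s_value,units
left_kidney,left_kidney,6.7e-4,Gy_per_MBq_h
right_kidney,right_kidney,6.7e-4,Gy_per_MBq_h
liver,liver,2.4e-5,Gy_per_MBq_h
spleen,spleen,1.5e-3,Gy_per_MBq_h
right_kidney,left_kidney,1.0e-6,Gy_per_MBq_h
left_kidney,right_kidney,1.0e-6,Gy_per_MBq_h
liver,left_kidney,5.0e-7,Gy_per_MBq_h
liver,right_kidney,5.0e-7,Gy_per_MBq_h
spleen,left_kidney,8.0e-7,Gy_per_MBq_h
left_kidney,liver,2.0e-7,Gy_per_MBq_h
right_kidney,liver,2.0e-7,Gy_per_MBq_h
spleen,liver,1.5e-7,Gy_per_MBq_h
left_kidney,spleen,9.0e-7,Gy_per_MBq_h
liver,spleen,4.0e-7,Gy_per_MBq_h
right_kidney,spleen,2.0e-7,Gy_per_MBq_h
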