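patient_code,n_monopolar,n_bipolar,lead_name,lead_type,tip_x_mm,tip_y_mm,tip_z_mm
P01,14,22,MDT3389,Standard,12.1,-4.9,-3.5
P02,14,28,MDT3389,Standard,8.8,-1.1,-4.6
P03,14,25,MDT3389,Standard,10.8,-3.9,-2.8
P04,33,9,ABT6172,Steerable,9.8,-4.9,-5.9
P05,39,10,BSC2202,Steerable,10.7,-2.5,-6.6
P06,34,6,ABT6172,Steerable,-12.7,-2.3,-4.2
P07,0,18,MDT3389,Standard,13.1,-5.4,-6.1
P08,14,20,MDT3389,Standard,13.4,-1.3,-4.1
P09,0,18,MDT3387,Standard,12.7,-2.4,-4.0
P10,9,18,BSC2201,Standard,9.3,-4.8,-7.3
P11,0,15,MDT3387,Standard,10.9,-1.6,-4.6
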