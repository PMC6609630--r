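# Healthy adult liver physiology.
# Q_HB is a calibration constant, not an independent physiological claim:
# it is the hepatic blood flow that makes the well-stirred back-calculation
# return CLu_int,H = 4.09 L/h from CL_H = 1.8 L/h, fu_p = 0.45, B:P = 1,
# matching the reference parameterization the other constants come from.
label: adult
Q_HB: 81.8          # L/h hepatic blood flow (calibrated, see above)
MPPGL: 38           # mg microsomal protein per g liver
liver_weight_g: 1637.7
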