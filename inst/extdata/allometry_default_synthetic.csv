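# Synthetic default allometric coefficients (dry biomass kg from DBH cm,
# y = beta1 * D^beta2 per compartment). Representative temperate-zone
# magnitudes for demonstration only, NOT published regression estimates:
# replace this file with a fitted coefficient table for real valuation work.
allometric_key,compartment,beta1,beta2
hardwood,wood,0.075,2.47
hardwood,bark,0.015,2.34
hardwood,branches,0.022,2.33
softwood,wood,0.045,2.46
softwood,bark,0.014,2.30
softwood,branches,0.021,2.26
Acer saccharum,wood,0.095,2.43
Acer saccharum,bark,0.017,2.35
Acer saccharum,branches,0.020,2.42
Picea glauca,wood,0.041,2.50
Picea glauca,bark,0.011,2.36
Picea glauca,branches,0.024,2.24
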