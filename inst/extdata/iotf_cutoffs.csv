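# International Obesity Task Force age- and sex-specific BMI cut-offs for
# overweight and obesity in youth (Cole TJ, Bellizzi MC, Flegal KM, Dietz WH.
# Establishing a standard definition for child overweight and obesity
# worldwide: international survey. BMJ 2000;320:1240-3).
# Cut-offs pass through the adult values 25 (overweight) and 30 (obesity)
# at age 18. Ages in half-year steps; BMI in kg/m^2.
age,sex,overweight,obesity
12,M,21.22,26.02
12.5,M,21.56,26.43
13,M,21.91,26.84
13.5,M,22.27,27.25
14,M,22.62,27.63
14.5,M,22.96,27.98
15,M,23.29,28.30
15.5,M,23.60,28.60
16,M,23.90,28.88
16.5,M,24.19,29.14
17,M,24.46,29.41
17.5,M,24.73,29.70
18,M,25.00,30.00
12,F,21.68,26.67
12.5,F,22.14,27.24
13,F,22.58,27.76
13.5,F,22.98,28.20
14,F,23.34,28.57
14.5,F,23.66,28.87
15,F,23.94,29.11
15.5,F,24.17,29.29
16,F,24.37,29.43
16.5,F,24.54,29.56
17,F,24.70,29.69
17.5,F,24.85,29.84
18,F,25.00,30.00
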