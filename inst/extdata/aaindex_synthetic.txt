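H LEVM760107
D van der Waals parameter (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.00  6.13  2.95  2.78  2.43  3.95  3.78  0.00  4.66  4.00
    4.00  4.77  4.43  5.89  2.72  1.60  2.60  8.08  6.47  3.00
//
H COHE430101
D Partial specific volume (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.74  0.70  0.62  0.60  0.63  0.67  0.66  0.64  0.67  0.90
    0.90  0.82  0.75  0.77  0.76  0.63  0.70  0.74  0.71  0.86
//
H CHAM820102
D Free energy of solution in water, kcal/mole (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.30  0.05  -0.35  -0.50  2.15  -0.20  -0.45  -0.15  0.25  0.35
    0.30  -0.10  -0.45  0.50  -0.50  -0.25  -0.10  2.45  2.30  0.30
//
H FAUJ880112
D Negative charge (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0  0  0  1  0  0  1  0  0  0
    0  0  0  0  0  0  0  0  0  0
//
H QIAN880115
D Weights for beta-sheet at the window position of -5 (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.05  -0.10  -0.22  -0.28  0.12  -0.05  -0.15  -0.35  0.02  0.40
    0.18  -0.12  0.10  0.30  -0.45  -0.08  0.20  0.28  0.32  0.45
//
H YUTK870102
D Unfolding Gibbs energy in water, pH9.0 (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    7.2  6.1  5.9  5.6  8.1  6.2  5.8  6.6  6.4  8.9
    8.6  5.7  7.9  8.8  6.0  6.3  6.7  9.2  7.8  8.5
//
H SYNT900101
D Synthetic incomplete hydration scale (missing Trp; exercises NA handling)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.42  1.30  1.05  1.25  0.29  1.10  1.27  0.48  0.87  0.22
    0.24  1.33  0.36  0.18  0.51  0.66  0.63  NA  0.44  0.20
//
H OOBM850102
D Optimized propensity to form reverse turn (synthetic stand-in values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.78  0.93  1.48  1.41  0.92  0.97  0.92  1.64  0.98  0.52
    0.56  1.04  0.68  0.60  1.52  1.34  1.06  0.48  0.74  0.51
//
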