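exp_mz,formula,adduct,theo_mz_printed,ppm_printed,identity,serum_detected,formula_is_neutral,note
436.2826,C_21_H_43_NO_6_P,[M-H]-,436.2834,1.8,LPE(P-16:0),TRUE,FALSE,computed theo 436.2833 and ppm 1.7
464.3139,C_23_H_47_NO_6_P,[M-H]-,464.3147,1.7,"LPE(O-18:1), LPE(P-18:0)",FALSE,FALSE,computed theo 464.3146 and ppm 1.6
465.3054,C_27_H_46_O_4_S,[M-H]-,465.3044,1.3,Cholesterol Sulfate,TRUE,TRUE,printed formula is the neutral molecule; computed ppm 2.1
480.3091,C_23_H_47_NO_7_P,[M-H]-,480.3096,0.8,LPE(18:0),TRUE,FALSE,computed ppm 1.0
524.2975,C_24_H_47_NO_9_P,[M-H]-,524.2994,3.6,LPS(18:0),TRUE,FALSE,
536.5044,C_34_H_66_NO_3_,[M-H]-,536.5048,0.9,Cer(d34:1),TRUE,FALSE,computed ppm 0.8
572.4827,C_34_H_67_NO_3_Cl,[M+Cl]-,572.4815,2.1,Cer(d34:1),FALSE,FALSE,
583.2567,C_33_H_36_N_4_O_6_,[M-H]-,583.2562,0.3,Bilirubin,TRUE,TRUE,printed formula is the neutral molecule; serum discriminatory marker; computed ppm 0.8
599.3209,C_27_H_52_O_12_P,[M-H]-,599.3202,1.2,LPI(18:0),TRUE,FALSE,
626.5328,C_38_H_73_NO_3_Cl,[M+Cl]-,626.5285,6.8,Cer(d38:2),FALSE,FALSE,computed theo 626.5284 and ppm 6.9
646.6124,C_42_H_80_NO_3_,[M-H]-,646.6144,3.1,Cer(d42:2),FALSE,FALSE,computed ppm 3.0
648.6272,C_42_H_82_NO_3_,[M-H]-,648.6300,5.9,Cer(d42:1),FALSE,FALSE,computed ppm 4.3
656.5800,C_40_H_79_NO_3_Cl,[M+Cl]-,656.5754,7.0,Cer(d40:1),FALSE,FALSE,
658.5919,C_40_H_81_NO_3_Cl,[M+Cl]-,658.5910,1.5,Cer(d40:0),FALSE,FALSE,computed ppm 1.3
682.5891,C_42_H_81_NO_3_Cl,[M+Cl]-,682.5911,2.9,Cer(d42:2),FALSE,FALSE,computed theo 682.5910; printed theo matches accompanying text
684.5952,C_42_H_83_NO_3_Cl,[M+Cl]-,684.6061,15.9,Cer(d42:1),FALSE,FALSE,accompanying text gives theo 684.6067 which matches computation; printed ppm follows the table value; computed ppm 16.8
737.5318,C_39_H_79_N_2_O_6_P,[M+Cl]-,737.5369,6.9,SM(d34:1),TRUE,FALSE,printed formula lacks the Cl of the adduct (treated as neutral); computed theo 737.5370 and ppm 7.0
847.6430,C_47_H_93_N_2_O_6_PCl,[M+Cl]-,847.6465,4.1,SM(d42:2),FALSE,FALSE,computed ppm 4.2
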