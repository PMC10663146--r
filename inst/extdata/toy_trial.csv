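id,arm,weight_change,chronic_first2y,cvd
1,a_low_caloric,loss,TRUE,TRUE
2,a_low_caloric,loss,TRUE,FALSE
3,a_low_caloric,loss,FALSE,TRUE
4,a_low_caloric,loss,FALSE,TRUE
5,a_low_caloric,loss,FALSE,FALSE
6,a_low_caloric,loss,FALSE,FALSE
7,a_low_caloric,loss,FALSE,FALSE
8,a_low_caloric,loss,FALSE,FALSE
9,a_low_caloric,loss,FALSE,FALSE
10,a_low_caloric,loss,FALSE,FALSE
11,a_low_caloric,loss,FALSE,FALSE
12,a_low_caloric,loss,FALSE,FALSE
13,a_low_caloric,loss,FALSE,FALSE
14,a_low_caloric,loss,FALSE,FALSE
15,a_low_caloric,loss,FALSE,FALSE
16,a_low_caloric,loss,FALSE,FALSE
17,a_low_caloric,loss,FALSE,FALSE
18,a_low_caloric,loss,FALSE,FALSE
19,a_low_caloric,loss,FALSE,FALSE
20,a_low_caloric,loss,FALSE,FALSE
21,b_standard_caloric,loss,TRUE,TRUE
22,b_standard_caloric,loss,TRUE,FALSE
23,b_standard_caloric,maintain,FALSE,TRUE
24,b_standard_caloric,maintain,FALSE,TRUE
25,b_standard_caloric,maintain,FALSE,FALSE
26,b_standard_caloric,maintain,FALSE,FALSE
27,b_standard_caloric,maintain,FALSE,FALSE
28,b_standard_caloric,maintain,FALSE,FALSE
29,b_standard_caloric,maintain,FALSE,FALSE
30,b_standard_caloric,maintain,FALSE,FALSE
31,b_standard_caloric,maintain,FALSE,FALSE
32,b_standard_caloric,maintain,FALSE,FALSE
33,b_standard_caloric,maintain,FALSE,FALSE
34,b_standard_caloric,maintain,FALSE,FALSE
35,b_standard_caloric,maintain,FALSE,FALSE
36,b_standard_caloric,maintain,FALSE,FALSE
37,b_standard_caloric,maintain,FALSE,FALSE
38,b_standard_caloric,maintain,FALSE,FALSE
39,b_standard_caloric,maintain,FALSE,FALSE
40,b_standard_caloric,maintain,FALSE,FALSE
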